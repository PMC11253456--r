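## Hand-built, minimal valid record frame for I/O and measurement tests.
tiny_records <- function(n = 3) {
  base <- data.frame(
    household_id = sprintf("hh%03d", seq_len(n)),
    kebele = "kebele_01",
    head_sex = rep(c("male", "female"), length.out = n),
    head_age = rep(c(25, 40, 70), length.out = n),
    marital_status = rep(c("married", "single", "widowed"), length.out = n),
    occupation = rep(c("self_employed", "government", "private_sector"),
                     length.out = n),
    family_size = rep(c(3, 5, 2), length.out = n),
    u5_present = rep(c(TRUE, FALSE), length.out = n),
    ownership = rep(c("private", "rent"), length.out = n),
    insurance = rep(c("insured", "non_insured"), length.out = n),
    chronic_condition = rep(c(FALSE, TRUE), length.out = n),
    traditional_medicine = rep(c(TRUE, FALSE), length.out = n),
    referral_history = rep(c("no", "yes", "missing"), length.out = n),
    food = rep(c(20000, 30000, 25000), length.out = n),
    nonfood_nonhealth = rep(c(10000, 8000, 12000), length.out = n),
    direct_medical = rep(c(1000, 4000, 0), length.out = n),
    direct_nonmedical = rep(c(200, 0, 100), length.out = n),
    lost_days = rep(c(0, 10, 3), length.out = n),
    daily_valuation = rep(c(150, 120, 100), length.out = n),
    stringsAsFactors = FALSE)
  base
}

## Strip non-structural attributes so record frames can be compared by value.
bare <- function(df) {
  attributes(df) <- attributes(df)[c("names", "row.names", "class")]
  df
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "chedecomp", mustWork = TRUE)
}

## A compact design spec (3 covariates, 6 columns) for tests where the full
## 20-column design would add nothing but runtime.
small_spec <- function() {
  c(head_age_group = "<=30", chronic_condition = "yes",
    traditional_medicine = "yes")
}
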