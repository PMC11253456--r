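test_that("the generator is fully determined by its seed", {
  cfg <- synthetic_config(n_insured = 50, n_non_insured = 80, seed = 9)
  g1 <- generate_outcome_level(cfg)
  g2 <- generate_outcome_level(cfg)
  expect_identical(g1, g2)

  e1 <- generate_expenditure_level(cfg)
  e2 <- generate_expenditure_level(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(e1$records, f1)
  write_survey(e2$records, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("invalid configurations are rejected", {
  marg <- default_marginals()
  marg$insured$head_sex <- c(male = 0.7, female = 0.4)  # sums to 1.1
  expect_error(synthetic_config(covariate_marginals = marg), "sum to 1")

  cfg <- synthetic_config(beta_insured = c(0, 1), beta_non_insured = c(0, 1),
                          n_insured = 50, n_non_insured = 50, seed = 1)
  expect_error(generate_outcome_level(cfg), "length")
})

test_that("configured group sizes are honored exactly", {
  gen <- generate_outcome_level(synthetic_config(seed = 20220524))
  expect_equal(as.integer(table(gen$records$insurance)[c("insured",
                                                         "non_insured")]),
               c(194L, 631L))
})

test_that("symmetric groups produce no gap", {
  marg <- default_marginals()
  marg$insured <- marg$non_insured
  cfg <- synthetic_config(n_insured = 1e4, n_non_insured = 1e4,
                          covariate_marginals = marg,
                          beta_insured = default_betas("non_insured"),
                          seed = 314)
  gen <- generate_outcome_level(cfg)
  expect_identical(gen$truth$population$R, 0)
  pA <- mean(gen$records$che[gen$records$insurance == "non_insured"])
  pB <- mean(gen$records$che[gen$records$insurance == "insured"])
  mc_se <- sqrt(pA * (1 - pA) / 1e4 + pB * (1 - pB) / 1e4)
  expect_lt(abs(pA - pB), 3 * mc_se)
})

test_that("identical marginals with different intercepts give zero endowment component", {
  marg <- default_marginals()
  marg$insured <- marg$non_insured
  bB <- default_betas("non_insured")
  bB[1] <- bB[1] - 0.8  # intercept shift only
  cfg <- synthetic_config(n_insured = 2000, n_non_insured = 2000,
                          covariate_marginals = marg, beta_insured = bB,
                          seed = 2718)
  gen <- generate_outcome_level(cfg)
  expect_identical(gen$truth$population$E, 0)
  res <- decompose_gap(gen$records)
  expect_lt(abs(res$E$estimate), 3 * res$E$se)
})

test_that("realized covariate frequencies recover the configured marginals", {
  n <- 1e5
  cfg <- synthetic_config(n_insured = n, n_non_insured = 2, seed = 555)
  gen <- generate_outcome_level(cfg)
  recs <- gen$records[gen$records$insurance == "insured", ]
  marg <- default_marginals()$insured
  for (v in names(marg)) {
    col <- recs[[v]]
    if (is.logical(col)) col <- ifelse(col, "yes", "no")
    for (cat in names(marg[[v]])) {
      p <- marg[[v]][[cat]]
      phat <- mean(col == cat)
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n) + 1e-12,
                label = sprintf("|freq - p| for %s=%s", v, cat))
    }
  }
})

test_that("expenditure calibration hits the target CHE prevalence within one point", {
  gen <- generate_expenditure_level(synthetic_config(seed = 8))
  flagged <- che_flag(gen$records, threshold = 0.10)
  expect_equal(nrow(flagged), 825)
  hc <- che_headcount(flagged)$proportion
  expect_gte(hc, 0.2994 - 0.01)
  expect_lte(hc, 0.2994 + 0.01)
})

test_that("a zero target with no health spending yields a zero headcount", {
  em <- default_expenditure_model()
  em$target_prevalence <- 0
  em$direct_medical <- list(meanlog = -Inf, sdlog = 0)
  em$direct_nonmedical <- list(meanlog = -Inf, sdlog = 0)
  em$lost_days_mean <- 0
  cfg <- synthetic_config(n_insured = 30, n_non_insured = 50,
                          expenditure_model = em, seed = 3)
  gen <- generate_expenditure_level(cfg)
  expect_equal(che_headcount(che_flag(gen$records))$count, 0)
})

test_that("an unattainable target is a calibration error", {
  em <- default_expenditure_model()
  em$target_prevalence <- 0
  ## non-medical spending alone already pushes many shares past 10%
  em$direct_nonmedical <- list(meanlog = log(4e4), sdlog = 0.1)
  cfg <- synthetic_config(n_insured = 30, n_non_insured = 50,
                          expenditure_model = em, seed = 3)
  expect_error(generate_expenditure_level(cfg), "calibration")
})
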