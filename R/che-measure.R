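#' Annual household health expenditure
#'
#' Sums the three cost channels over the 12-month recall window: direct
#' medical spending, direct non-medical spending (transport, cafeteria,
#' lodging), and indirect costs valued by the human-capital approach as
#' lost days (patient plus caregiver) times a per-household daily valuation.
#' Pre-monetized losses (premature death, early retirement) are folded into
#' `lost_days * daily_valuation` by the data supplier.
#'
#' @param records Household records (or any data frame) with numeric columns
#'   `direct_medical`, `direct_nonmedical`, `lost_days`, `daily_valuation`.
#' @return Numeric vector of annual health expenditure, one per row.
#' @examples
#' annual_health_expenditure(data.frame(direct_medical = 100,
#'   direct_nonmedical = 20, lost_days = 5, daily_valuation = 10))  # 170
#' @export
annual_health_expenditure <- function(records) {
  records$direct_medical + records$direct_nonmedical +
    records$lost_days * records$daily_valuation
}

#' Flag catastrophic health expenditure
#'
#' Computes each household's health-expenditure share and flags it as
#' catastrophic when the share strictly exceeds the threshold. The default
#' denominator is total household expenditure with health spending included
#' (budget-share convention); alternatives are exposed because threshold
#' practice varies: `denominator_kind = "nonfood"` uses total minus food, and
#' `include_health = FALSE` excludes health spending from the denominator.
#'
#' Households with a non-positive denominator have an undefined share; they
#' are excluded with a row-indexed diagnostic (attribute `"excluded"`).
#'
#' @param records Household records with expenditure columns.
#' @param threshold Catastrophe threshold, a fraction in `[0.10, 0.40]`
#'   (default 0.10).
#' @param denominator_kind `"total"` (default) or `"nonfood"`.
#' @param include_health Logical; include health expenditure in the total
#'   (default `TRUE`).
#' @return `records` augmented with columns `health_expenditure`,
#'   `denominator_expenditure`, `che_share`, and logical `che`; rows with a
#'   non-positive denominator dropped and reported in attribute `"excluded"`.
#' @export
che_flag <- function(records, threshold = 0.10,
                     denominator_kind = c("total", "nonfood"),
                     include_health = TRUE) {
  denominator_kind <- match.arg(denominator_kind)
  if (!is_scalar_number(threshold) || threshold < 0.10 || threshold > 0.40) {
    stop("threshold must be a fraction in [0.10, 0.40]", call. = FALSE)
  }
  health <- annual_health_expenditure(records)
  total <- records$food + records$nonfood_nonhealth +
    if (include_health) health else 0
  denom <- switch(denominator_kind, total = total, nonfood = total - records$food)

  bad <- which(denom <= 0)
  excluded <- data.frame(row = bad,
                         reason = rep("non-positive denominator", length(bad)))
  if (length(bad)) {
    warning(length(bad), " household(s) excluded: undefined share ",
            "(non-positive denominator)", call. = FALSE)
    records <- records[-bad, , drop = FALSE]
    health <- health[-bad]
    denom <- denom[-bad]
  }
  records$health_expenditure <- health
  records$denominator_expenditure <- denom
  records$che_share <- health / denom
  records$che <- records$che_share > threshold
  attr(records, "che_threshold") <- threshold
  attr(records, "denominator_kind") <- denominator_kind
  attr(records, "excluded") <- excluded
  rownames(records) <- NULL
  records
}

#' Catastrophic-expenditure headcount
#'
#' Counts flagged households and reports the headcount proportion. With a
#' `stratum`, two conventions are reported side by side: the within-stratum
#' proportion (flagged in stratum / stratum size) and the share-of-total
#' proportion (flagged in stratum / full analytic sample) — survey reports
#' use both, and they answer different questions, so neither is dropped.
#'
#' @param records Records carrying a logical `che` column (e.g. from
#'   [che_flag()] or the outcome-level generator).
#' @param stratum Optional insurance stratum label (`"insured"` or
#'   `"non_insured"`) to restrict the numerator to.
#' @return List with `count`, `n`, `proportion` (and for a stratum also
#'   `n_stratum`, `within_stratum`, `share_of_total`).
#' @export
che_headcount <- function(records, stratum = NULL) {
  if (!nrow(records)) stop("empty record collection", call. = FALSE)
  if (!is.logical(records$che)) stop("records lack a logical 'che' column",
                                     call. = FALSE)
  n <- nrow(records)
  if (is.null(stratum)) {
    k <- sum(records$che)
    return(list(count = k, n = n, proportion = k / n))
  }
  stopifnot(stratum %in% survey_vocabulary()$insurance)
  in_s <- records$insurance == stratum
  k <- sum(records$che & in_s)
  list(count = k, n = n, n_stratum = sum(in_s),
       within_stratum = k / sum(in_s),
       share_of_total = k / n,
       proportion = k / n)
}
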