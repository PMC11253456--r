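#' Default per-group covariate category probabilities
#'
#' Group-specific marginal distributions for the generator, patterned on a
#' two-stratum Ethiopian town household survey with community-based health
#' insurance: insured households skew older, more self-employed and poorer
#' on the asset index; non-insured households skew government-employed and
#' renters. Covariates are drawn independently within group (the minimal
#' assumption when only marginals are specified).
#'
#' @return Named list with elements `insured` and `non_insured`; each a list
#'   of per-covariate named probability vectors (each summing to 1).
#' @export
default_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    insured = list(
      head_sex = norm(c(male = 127, female = 67)),
      head_age_group = norm(c("<=30" = 33, "31-45" = 73, "46-60" = 56,
                              ">60" = 32)),
      marital_status = norm(c(single = 18, married = 116, separated = 5,
                              divorced = 20, widowed = 35)),
      u5_present = norm(c(yes = 61, no = 133)),
      family_size_cat = norm(c("<=4" = 143, ">4" = 51)),
      occupation = norm(c(self_employed = 158, government = 19,
                          private_sector = 17)),
      wealth_status = norm(c(poorest = 67, poorer = 52, middle = 29,
                             richer = 26, richest = 20)),
      ownership = norm(c(private = 125, rent = 69)),
      chronic_condition = norm(c(yes = 70, no = 124)),
      traditional_medicine = norm(c(yes = 35, no = 159)),
      referral_history = norm(c(yes = 6, no = 154, missing = 34))
    ),
    non_insured = list(
      head_sex = norm(c(male = 447, female = 184)),
      head_age_group = norm(c("<=30" = 158, "31-45" = 270, "46-60" = 126,
                              ">60" = 77)),
      marital_status = norm(c(single = 37, married = 457, separated = 23,
                              divorced = 54, widowed = 60)),
      u5_present = norm(c(yes = 200, no = 431)),
      family_size_cat = norm(c("<=4" = 485, ">4" = 146)),
      occupation = norm(c(self_employed = 241, government = 366,
                          private_sector = 24)),
      wealth_status = norm(c(poorest = 96, poorer = 108, middle = 132,
                             richer = 153, richest = 142)),
      ownership = norm(c(private = 396, rent = 235)),
      chronic_condition = norm(c(yes = 179, no = 452)),
      traditional_medicine = norm(c(yes = 143, no = 488)),
      referral_history = norm(c(yes = 35, no = 500, missing = 96))
    )
  )
}

#' Default group-specific logit coefficients for the CHE outcome
#'
#' Coefficient vectors on the columns of the default design
#' ([default_design_spec()]; intercept first). Magnitudes are moderate
#' (|beta| <= 1.6) so that realistic group sizes avoid separation; the
#' intercepts put within-group CHE incidence near 0.25 (non-insured) and
#' 0.15 (insured), the qualitative pattern of an insurance scheme that
#' dampens — but does not remove — expenditure risk, with attenuated
#' covariate effects in the insured group.
#'
#' @param group `"insured"` or `"non_insured"`.
#' @return Named numeric coefficient vector (20 components).
#' @export
default_betas <- function(group = c("non_insured", "insured")) {
  group <- match.arg(group)
  nm <- c("(Intercept)", "head_sexfemale", "head_age_group31-45",
          "head_age_group46-60", "head_age_group>60",
          "marital_statusmarried", "marital_statusseparated",
          "marital_statusdivorced", "marital_statuswidowed",
          "u5_presentyes", "family_size_cat>4", "occupationgovernment",
          "occupationprivate_sector", "wealth_statuspoorer",
          "wealth_statusmiddle", "wealth_statusricher",
          "wealth_statusrichest", "ownershiprent",
          "chronic_conditionno", "traditional_medicineno")
  b <- switch(group,
    non_insured = c(-0.60, -0.20, 0.30, 0.80, 1.20,
                    0.20, -0.10, 0.60, 0.50,
                    -0.10, 0.30, 0.40, 0.60,
                    -0.10, 0.20, 0.60, 0.20, -0.40,
                    -1.60, -0.70),
    insured     = c(-1.20, -0.10, 0.10, 0.40, 0.60,
                    0.10, -0.10, 0.30, 0.30,
                    -0.10, 0.10, 0.30, 0.30,
                    -0.10, 0.10, 0.30, 0.10, -0.20,
                    -1.20, -0.50))
  stats::setNames(b, nm)
}

#' Default expenditure model
#'
#' Annual amounts are lognormal (strictly positive, right-skewed — the
#' standard shape for household spending); lost days are Poisson and valued
#' at a flat daily rate. The `direct_medical` scale is later calibrated by
#' bisection to hit the target CHE prevalence, so its `meanlog` sets only
#' the pre-calibration order of magnitude.
#'
#' @return List of component parameters and the target CHE prevalence at the
#'   10% threshold (scalar, or named per-group vector
#'   `c(insured = , non_insured = )`).
#' @export
default_expenditure_model <- function() {
  list(food = list(meanlog = log(30000), sdlog = 0.5),
       nonfood_nonhealth = list(meanlog = log(15000), sdlog = 0.6),
       direct_medical = list(meanlog = log(1500), sdlog = 1.2),
       direct_nonmedical = list(meanlog = log(250), sdlog = 1.0),
       lost_days_mean = 4,
       daily_valuation = 150,
       target_prevalence = 0.2994)
}

#' Default one-factor asset model
#'
#' Each household has a standard-normal latent wealth score; every asset is
#' Bernoulli with probability `plogis(qlogis(base) + loading * z)`, giving a
#' PCA-recoverable one-factor structure. Base prevalences span 0.10-0.90.
#'
#' @param n_assets Number of asset indicators (default 35).
#' @param loading Common latent loading (default 1.2).
#' @return List with `base_prevalence` (named) and `loading`.
#' @export
default_asset_model <- function(n_assets = 35, loading = 1.2) {
  list(base_prevalence = stats::setNames(
         seq(0.10, 0.90, length.out = n_assets),
         sprintf("asset_%02d", seq_len(n_assets))),
       loading = loading)
}

#' Configure the synthetic household-survey generator
#'
#' @param n_insured,n_non_insured Group sizes (defaults 194 and 631).
#' @param covariate_marginals Per-group category probabilities; see
#'   [default_marginals()]. Every table must sum to 1 (tolerance 1e-12).
#' @param beta_insured,beta_non_insured Logit coefficient vectors (including
#'   intercept) on the design implied by `design_spec`.
#' @param design_spec Covariates (with reference levels) entering the
#'   outcome model; see [default_design_spec()].
#' @param expenditure_model See [default_expenditure_model()].
#' @param asset_model See [default_asset_model()].
#' @param seed Integer; fully determines the generated sample.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_insured = 194, n_non_insured = 631,
                             covariate_marginals = default_marginals(),
                             beta_insured = default_betas("insured"),
                             beta_non_insured = default_betas("non_insured"),
                             design_spec = default_design_spec(),
                             expenditure_model = default_expenditure_model(),
                             asset_model = default_asset_model(),
                             seed = 1L) {
  stopifnot(n_insured >= 1, n_non_insured >= 1)
  for (g in c("insured", "non_insured")) {
    for (v in names(covariate_marginals[[g]])) {
      pr <- covariate_marginals[[g]][[v]]
      if (abs(sum(pr) - 1) > 1e-12 || any(pr < 0)) {
        stop("marginal probabilities for '", v, "' (", g,
             ") must be non-negative and sum to 1", call. = FALSE)
      }
    }
    need <- setdiff(names(design_spec), names(covariate_marginals[[g]]))
    if (length(need)) {
      stop("marginals missing for design covariate(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_insured = as.integer(n_insured),
                 n_non_insured = as.integer(n_non_insured),
                 covariate_marginals = covariate_marginals,
                 beta_insured = beta_insured,
                 beta_non_insured = beta_non_insured,
                 design_spec = design_spec,
                 expenditure_model = expenditure_model,
                 asset_model = asset_model,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## Draw one group's covariate frame from its marginals (independent draws).
draw_covariates <- function(n, marg, group, id_offset = 0L) {
  draw <- function(pr) sample(names(pr), n, replace = TRUE, prob = pr)
  age_group <- draw(marg$head_age_group)
  age <- numeric(n)
  rng <- list("<=30" = 18:30, "31-45" = 31:45, "46-60" = 46:60, ">60" = 61:90)
  for (g in names(rng)) {
    k <- age_group == g
    age[k] <- sample(rng[[g]], sum(k), replace = TRUE)
  }
  fam_cat <- draw(marg$family_size_cat)
  fam <- as.numeric(ifelse(fam_cat == "<=4", sample(1:4, n, replace = TRUE),
                           sample(5:10, n, replace = TRUE)))
  data.frame(
    household_id = sprintf("hh%05d", id_offset + seq_len(n)),
    kebele = sample(c("kebele_01", "kebele_03", "kebele_04"), n,
                    replace = TRUE),
    head_sex = draw(marg$head_sex),
    head_age = age,
    head_age_group = age_group,
    marital_status = draw(marg$marital_status),
    occupation = draw(marg$occupation),
    family_size = fam,
    family_size_cat = fam_cat,
    u5_present = draw(marg$u5_present) == "yes",
    ownership = draw(marg$ownership),
    insurance = group,
    chronic_condition = draw(marg$chronic_condition) == "yes",
    traditional_medicine = draw(marg$traditional_medicine) == "yes",
    wealth_status = draw(marg$wealth_status),
    referral_history = draw(marg$referral_history),
    stringsAsFactors = FALSE)
}

## Exact population E/C under the config: enumerate the full cell grid of
## the independent marginals (feasible because covariates are categorical)
## and weight counterfactual logistic means by cell probabilities.
population_truth <- function(config) {
  spec <- config$design_spec
  marg_A <- config$covariate_marginals$non_insured[names(spec)]
  marg_B <- config$covariate_marginals$insured[names(spec)]
  grid <- expand.grid(lapply(marg_A, names), stringsAsFactors = FALSE)
  names(grid) <- names(spec)
  wA <- rep(1, nrow(grid)); wB <- rep(1, nrow(grid))
  for (v in names(spec)) {
    wA <- wA * unname(marg_A[[v]][grid[[v]]])
    wB <- wB * unname(marg_B[[v]][grid[[v]]])
  }
  ## reuse the design builder so coding is identical to estimation
  gframe <- grid
  for (v in c("u5_present", "chronic_condition", "traditional_medicine")) {
    if (v %in% names(gframe)) gframe[[v]] <- gframe[[v]] == "yes"
  }
  gframe$family_size <- ifelse(gframe$family_size_cat == "<=4", 2L, 6L)
  X <- build_design(gframe, spec, outcome = NULL)$X
  bA <- config$beta_non_insured; bB <- config$beta_insured
  pA  <- sum(wA * stats::plogis(drop(X %*% bA)))
  pBA <- sum(wB * stats::plogis(drop(X %*% bA)))
  pB  <- sum(wB * stats::plogis(drop(X %*% bB)))
  list(R = pA - pB, E = pA - pBA, C = pBA - pB)
}

#' Generate an outcome-level synthetic sample
#'
#' Draws covariates independently from the per-group marginals and the CHE
#' flag as Bernoulli with probability `plogis(x' beta_group)`. Returns the
#' realized records together with the generating parameters and the true
#' decomposition components, computed two ways: over the realized designs
#' (the estimand the fitted decomposition targets, conditional on X) and
#' over the exact population cell grid (free of design noise; identically
#' distributed marginals give population E = 0 exactly).
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (the CHE flag in logical column `che`) and
#'   `truth` (betas, realized and population `R`/`E`/`C`).
#' @export
generate_outcome_level <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- config$design_spec
  bA <- config$beta_non_insured
  bB <- config$beta_insured
  withr::with_seed(config$seed, {
    recs_B <- draw_covariates(config$n_insured,
                              config$covariate_marginals$insured, "insured")
    recs_A <- draw_covariates(config$n_non_insured,
                              config$covariate_marginals$non_insured,
                              "non_insured", id_offset = config$n_insured)
    XA <- build_design(recs_A, spec, outcome = NULL, check_levels = FALSE)$X
    XB <- build_design(recs_B, spec, outcome = NULL, check_levels = FALSE)$X
    if (ncol(XA) != length(bA) || ncol(XB) != length(bB)) {
      stop("config error: coefficient vector length (", length(bA), "/",
           length(bB), ") does not match design columns (", ncol(XA), ")",
           call. = FALSE)
    }
    pA_i <- stats::plogis(drop(XA %*% bA))
    pB_i <- stats::plogis(drop(XB %*% bB))
    recs_A$che <- stats::runif(nrow(recs_A)) < pA_i
    recs_B$che <- stats::runif(nrow(recs_B)) < pB_i
    records <- rbind(recs_B, recs_A)
    records <- fill_placeholder_expenditures(records)
    realized <- list(
      R = mean(stats::plogis(drop(XA %*% bA))) -
        mean(stats::plogis(drop(XB %*% bB))),
      E = mean(stats::plogis(drop(XA %*% bA))) -
        mean(stats::plogis(drop(XB %*% bA))),
      C = mean(stats::plogis(drop(XB %*% bA))) -
        mean(stats::plogis(drop(XB %*% bB))))
    list(records = records,
         truth = list(beta_non_insured = bA, beta_insured = bB,
                      design_spec = spec,
                      realized = realized,
                      population = population_truth(config)))
  })
}

## Outcome-level samples carry the CHE flag directly; expenditure fields are
## zero-filled so records still satisfy the shared data model.
fill_placeholder_expenditures <- function(records) {
  for (f in c("food", "nonfood_nonhealth", "direct_medical",
              "direct_nonmedical", "lost_days")) {
    if (!f %in% names(records)) records[[f]] <- 0
  }
  if (!"daily_valuation" %in% names(records)) records$daily_valuation <- 0
  records
}

#' Generate an expenditure-level synthetic sample
#'
#' Draws covariates, a one-factor asset inventory linked to a latent
#' standard-normal wealth score, and lognormal expenditure components, then
#' calibrates the `direct_medical` scale by bisection until the realized
#' CHE headcount at the 10% threshold is within ±1 percentage point of the
#' configured target (per group when the target is a named per-group
#' vector, otherwise overall). The same seed always yields byte-identical
#' output.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (full expenditure and asset columns) and
#'   `truth` (`latent_wealth` per household, calibrated `medical_scale`).
#' @export
generate_expenditure_level <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  em <- config$expenditure_model
  am <- config$asset_model
  withr::with_seed(config$seed, {
    recs_B <- draw_covariates(config$n_insured,
                              config$covariate_marginals$insured, "insured")
    recs_A <- draw_covariates(config$n_non_insured,
                              config$covariate_marginals$non_insured,
                              "non_insured", id_offset = config$n_insured)
    records <- rbind(recs_B, recs_A)
    records$wealth_status <- NULL  # to be reconstructed from assets
    n <- nrow(records)

    z <- stats::rnorm(n)
    for (a in names(am$base_prevalence)) {
      p <- stats::plogis(stats::qlogis(am$base_prevalence[[a]]) +
                           am$loading * z)
      records[[a]] <- stats::runif(n) < p
    }

    records$food <- stats::rlnorm(n, em$food$meanlog, em$food$sdlog)
    records$nonfood_nonhealth <- stats::rlnorm(n, em$nonfood_nonhealth$meanlog,
                                               em$nonfood_nonhealth$sdlog)
    med0 <- stats::rlnorm(n, em$direct_medical$meanlog, em$direct_medical$sdlog)
    records$direct_nonmedical <- stats::rlnorm(n, em$direct_nonmedical$meanlog,
                                               em$direct_nonmedical$sdlog)
    records$lost_days <- as.numeric(stats::rpois(n, em$lost_days_mean))
    records$daily_valuation <- rep(em$daily_valuation, n)

    target <- em$target_prevalence
    scale_for <- function(idx, tgt) {
      calibrate_medical_scale(med0[idx], records[idx, , drop = FALSE], tgt)
    }
    if (length(target) == 1L && is.null(names(target))) {
      s <- scale_for(seq_len(n), target)
      records$direct_medical <- med0 * s
      medical_scale <- c(overall = s)
    } else {
      medical_scale <- c(insured = NA_real_, non_insured = NA_real_)
      records$direct_medical <- med0
      for (g in c("insured", "non_insured")) {
        idx <- which(records$insurance == g)
        s <- scale_for(idx, target[[g]])
        records$direct_medical[idx] <- med0[idx] * s
        medical_scale[[g]] <- s
      }
    }
    ## currency rounding (2 dp) keeps file round-trips exact
    for (f in c("food", "nonfood_nonhealth", "direct_medical",
                "direct_nonmedical")) {
      records[[f]] <- round(records[[f]], 2)
    }
    list(records = records,
         truth = list(latent_wealth = z, medical_scale = medical_scale))
  })
}

## Bisection on the direct_medical multiplier; the headcount is monotone in
## the scale because health spending enters both numerator and denominator
## but dominates the numerator.
calibrate_medical_scale <- function(med0, records, target, tol = 0.01,
                                    max_iter = 100) {
  stopifnot(target >= 0, target <= 1)
  headcount_at <- function(s) {
    r <- records
    r$direct_medical <- med0 * s
    mean(suppressWarnings(che_flag(r, threshold = 0.10))$che)
  }
  if (headcount_at(0) > target + tol) {
    stop("calibration error: headcount at zero medical spending (",
         round(headcount_at(0), 4), ") already exceeds target ", target,
         call. = FALSE)
  }
  lo <- 0; hi <- 1
  it <- 0
  while (headcount_at(hi) < target - tol && it < max_iter) {
    hi <- hi * 4; it <- it + 1
  }
  if (headcount_at(hi) < target - tol) {
    stop("calibration error: target prevalence ", target,
         " unattainable within scale bounds", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    h <- headcount_at(mid)
    if (abs(h - target) <= tol) return(mid)
    if (h < target) lo <- mid else hi <- mid
  }
  stop("calibration error: bisection did not reach target ", target,
       " within ", max_iter, " iterations", call. = FALSE)
}
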