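#' Prevalence filter for asset indicators
#'
#' Drops binary asset indicators that are nearly universal or nearly absent:
#' a variable is retained when its positive-response frequency `p` satisfies
#' `low <= p <= high` (boundaries inclusive — the exclusion rule is strictly
#' "greater than `high`" / "less than `low`"). Near-constant indicators carry
#' almost no wealth signal and destabilize a correlation-matrix PCA.
#'
#' @param assets Logical matrix or data frame of asset indicators (households
#'   in rows).
#' @param low,high Retention band for the positive frequency; defaults 0.05
#'   and 0.95.
#' @return List with `retained` (names) and `removal_log` (data frame of
#'   `variable`, `prevalence`, `reason`).
#' @export
filter_by_prevalence <- function(assets, low = 0.05, high = 0.95) {
  assets <- as.data.frame(assets)
  stopifnot(low < high)
  p <- vapply(assets, function(v) mean(as.logical(v)), numeric(1))
  drop_hi <- p > high
  drop_lo <- p < low
  removal_log <- data.frame(
    variable = names(p)[drop_hi | drop_lo],
    prevalence = unname(p[drop_hi | drop_lo]),
    reason = ifelse(p[drop_hi | drop_lo] > high,
                    sprintf("prevalence>%g", high),
                    sprintf("prevalence<%g", low)))
  list(retained = names(p)[!(drop_hi | drop_lo)], removal_log = removal_log)
}

#' Correlation filter for asset indicators
#'
#' Iteratively removes indicators whose pairwise correlations fall outside
#' the band `[low, high]` in absolute value. Entry-wise deletion is undefined
#' for a PCA input, so the rule is applied greedily per variable: at each
#' round the variable with the greatest number of out-of-band pairwise
#' correlations is removed (ties broken by lower prevalence first, then
#' lexicographic name), correlations are recomputed, and the loop stops when
#' no violations remain or `min_keep` variables are left. Every removal is
#' logged with its round and violation count.
#'
#' @param assets Logical matrix/data frame over the currently retained names.
#' @param low,high Absolute-correlation band; defaults 0.1 and 0.9.
#' @param min_keep Minimum number of survivors (default 3); reaching it
#'   triggers a warning, not an error.
#' @return List with `retained` and `removal_log` (data frame of `variable`,
#'   `round`, `violations`, `reason`).
#' @export
filter_by_correlation <- function(assets, low = 0.1, high = 0.9,
                                  min_keep = 3) {
  assets <- as.data.frame(lapply(as.data.frame(assets),
                                 function(v) as.numeric(as.logical(v))))
  if (ncol(assets) < 2) stop("need at least 2 variables", call. = FALSE)
  keep <- names(assets)
  log_rows <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    X <- assets[, keep, drop = FALSE]
    r <- suppressWarnings(stats::cor(X))
    r[is.na(r)] <- 0  # zero-variance column: correlates with nothing
    a <- abs(r)
    diag(a) <- NA
    viol <- rowSums(a < low | a > high, na.rm = TRUE)
    if (max(viol) == 0) break
    if (length(keep) <= min_keep) {
      warning("correlation filter stopped at the minimum of ", min_keep,
              " variables with violations remaining", call. = FALSE)
      break
    }
    worst <- which(viol == max(viol))
    if (length(worst) > 1) {
      prev <- colMeans(X[, worst, drop = FALSE])
      worst <- worst[order(prev, names(viol)[worst])]
    }
    victim <- names(viol)[worst[1]]
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      variable = victim, round = round_i,
      violations = unname(viol[worst[1]]),
      reason = sprintf("|r| outside [%g,%g] with %d variable(s)",
                       low, high, unname(viol[worst[1]])))
    keep <- setdiff(keep, victim)
  }
  if (length(keep) < 3) {
    warning("fewer than 3 variables survive the correlation filter",
            call. = FALSE)
  }
  removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(variable = character(), round = integer(),
               violations = integer(), reason = character())
  list(retained = keep, removal_log = removal_log)
}

#' Fit an asset-based wealth model
#'
#' Standardizes the (already filtered) binary asset matrix and extracts the
#' first principal component of the correlation matrix; the component is the
#' wealth score. Binary indicators with heterogeneous prevalence make the
#' covariance PCA prevalence-driven, hence the standardized (correlation)
#' form. The loading vector has unit norm and is oriented so that the anchor
#' variable (default: the highest-prevalence asset) loads positively —
#' owning a common durable asset should raise, not lower, the score.
#' Quintile cutpoints are the 20/40/60/80 rank percentiles of the in-sample
#' scores.
#'
#' @param assets Logical matrix/data frame of retained asset indicators;
#'   at least 3 variables and 10 households.
#' @param anchor Orientation anchor variable name; default highest-prevalence.
#' @return Object of class `wealth_model`: `retained`, `loadings`,
#'   `center`, `scale`, `cutpoints`, `anchor`, `var_explained`.
#' @export
fit_wealth_model <- function(assets, anchor = NULL) {
  X <- as.data.frame(lapply(as.data.frame(assets),
                            function(v) as.numeric(as.logical(v))))
  if (ncol(X) < 3) stop("need >= 3 asset variables", call. = FALSE)
  if (nrow(X) < 10) stop("need >= 10 households", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("zero-variance asset variable(s): ",
         paste(names(X)[sds == 0], collapse = ", "),
         " (prevalence filter should have removed these)", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  anchor <- anchor %||% names(X)[which.max(colMeans(X))]
  if (!anchor %in% names(X)) stop("anchor variable '", anchor,
                                  "' not among assets", call. = FALSE)
  if (loadings[anchor] < 0) loadings <- -loadings
  score <- as.numeric(scale(X, center = pc$center, scale = pc$scale) %*% loadings)
  cutpoints <- stats::quantile(score, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  if (any(diff(cutpoints) <= 0)) {
    warning("quintile cutpoints are not strictly increasing ",
            "(heavy score ties)", call. = FALSE)
  }
  structure(list(retained = names(X), loadings = loadings,
                 center = pc$center, scale = pc$scale,
                 cutpoints = cutpoints, anchor = anchor,
                 var_explained = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "wealth_model")
}

#' Score households on a fitted wealth model
#'
#' @param model A `wealth_model`.
#' @param assets Asset indicators including every retained variable.
#' @return Numeric score vector.
#' @export
wealth_score <- function(model, assets) {
  assets <- as.data.frame(assets)
  missing <- setdiff(model$retained, names(assets))
  if (length(missing)) {
    stop("schema error: asset variable(s) absent: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(lapply(assets[model$retained],
                                      function(v) as.numeric(as.logical(v)))))
  as.numeric(scale(X, center = model$center, scale = model$scale) %*%
               model$loadings)
}

#' Assign wealth quintiles
#'
#' Bins scores at the model's rank-percentile cutpoints, labels ascending in
#' score (`poorest` ... `richest`). All households sharing a tied score land
#' in the same bin, so bin sizes need not be equal — with clustered asset
#' patterns, unequal quintile sizes are the expected outcome, not an error.
#'
#' @param model A `wealth_model`.
#' @param assets Asset indicators for the households to classify.
#' @return Factor of quintile labels, ordered `poorest < ... < richest`.
#' @export
assign_quintiles <- function(model, assets) {
  score <- wealth_score(model, assets)
  if (length(unique(score)) == 1L) {
    warning("all households share one wealth score; single quintile assigned",
            call. = FALSE)
  }
  labels <- survey_vocabulary()$wealth_status
  bin <- 1L + rowSums(outer(score, model$cutpoints, `>`))
  factor(labels[bin], levels = labels, ordered = TRUE)
}

#' Build a wealth index end-to-end
#'
#' Runs the full construction on raw records: prevalence filter,
#' iterative correlation filter, first-component PCA, and quintile
#' assignment.
#'
#' @param records Household records with `asset_*` columns.
#' @param low_prev,high_prev Prevalence retention band (defaults 0.05, 0.95).
#' @param low_cor,high_cor Absolute-correlation band (defaults 0.1, 0.9).
#' @param anchor Optional orientation anchor.
#' @return List with the fitted `model`, the combined `removal_log`,
#'   `quintile` (factor per household), and `score`.
#' @export
build_wealth_index <- function(records, low_prev = 0.05, high_prev = 0.95,
                               low_cor = 0.1, high_cor = 0.9, anchor = NULL) {
  asset_cols <- grep("^asset_", names(records), value = TRUE)
  if (length(asset_cols) < 3) stop("records carry fewer than 3 asset columns",
                                   call. = FALSE)
  assets <- records[asset_cols]
  f1 <- filter_by_prevalence(assets, low_prev, high_prev)
  f2 <- filter_by_correlation(assets[f1$retained], low_cor, high_cor)
  model <- fit_wealth_model(assets[f2$retained], anchor = anchor)
  log1 <- if (nrow(f1$removal_log)) cbind(f1$removal_log[c("variable", "reason")],
                                          stage = "prevalence") else NULL
  log2 <- if (nrow(f2$removal_log)) cbind(f2$removal_log[c("variable", "reason")],
                                          stage = "correlation") else NULL
  model$candidates <- asset_cols
  list(model = model,
       removal_log = rbind(log1, log2),
       score = wealth_score(model, assets),
       quintile = assign_quintiles(model, assets))
}

#' Serialize a wealth model to JSON
#'
#' @param model A `wealth_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wealth_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
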