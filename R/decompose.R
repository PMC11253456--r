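## ---- twofold logit decomposition -------------------------------------------
##
## For groups A (comparison, default non-insured) and B (reference, default
## insured), with F the logistic cdf and row-wise means over each group's
## observed design:
##
##   R = mean F(X_A b_A) - mean F(X_B b_B)          (raw probability gap)
##     = [mean F(X_A b_A) - mean F(X_B b_A)]        E: endowments  (explained)
##     + [mean F(X_B b_A) - mean F(X_B b_B)]        C: coefficients (unexplained)
##
## Detailed attribution uses Yun first-order weights:
##   E_k = E * bA_k (XbarA_k - XbarB_k) / sum_j bA_j (XbarA_j - XbarB_j)
##   C_k = C * XbarB_k (bA_k - bB_k)   / sum_j XbarB_j (bA_j - bB_j)
## with the intercept carried among the C terms (Xbar component 1).

## Deviation-from-mean normalization: re-expresses each categorical block so
## every level (including the reference) carries a coefficient summing to
## zero within the block; the linear predictor is unchanged, but detailed
## contributions become invariant to the reference-level choice.
## Returns the linear map T (beta* = T beta) and the expanded term map.
normalization_transform <- function(terms, spec) {
  vars <- setdiff(unique(terms$variable), "(Intercept)")
  K <- nrow(terms)
  rows <- list(data.frame(term = "(Intercept)", variable = "(Intercept)",
                          level = NA_character_))
  Tm <- matrix(0, nrow = 0, ncol = K, dimnames = list(NULL, terms$column))
  t_int <- numeric(K); t_int[terms$variable == "(Intercept)"] <- 1
  for (v in vars) {
    idx <- which(terms$variable == v)
    m <- length(idx)
    t_int[idx] <- t_int[idx] + 1 / (m + 1)
    ref <- spec[[v]]
    block <- matrix(-1 / (m + 1), nrow = m + 1, ncol = m)
    block[-1, ] <- block[-1, ] + diag(m)
    Tv <- matrix(0, nrow = m + 1, ncol = K)
    Tv[, idx] <- block
    Tm <- rbind(Tm, Tv)
    rows[[length(rows) + 1L]] <- data.frame(
      term = paste0(v, c(ref, terms$level[idx])),
      variable = v, level = c(ref, terms$level[idx]))
  }
  Tm <- rbind(t_int, Tm)
  list(T = Tm, terms = do.call(rbind, rows))
}

## Expanded design-column means under normalization: the reference level's
## mean is 1 - (sum of its block's dummy means).
normalized_xbar <- function(xbar, terms, spec) {
  out <- c("(Intercept)" = 1)
  for (v in setdiff(unique(terms$variable), "(Intercept)")) {
    idx <- which(terms$variable == v)
    out <- c(out, 1 - sum(xbar[idx]), xbar[idx])
  }
  unname(out)
}

#' Yun first-order attribution weights
#'
#' @param beta_A,beta_B Coefficient vectors (comparison and reference group).
#' @param xbar_A,xbar_B Design-column means per group (intercept included,
#'   component 1).
#' @return List with `w_E`, `w_C` (each summing to 1 within its family),
#'   the raw numerators, and instability flags set when a weight denominator
#'   vanishes (|denominator| < 1e-12), in which case that family's weights
#'   are returned as zeros.
#' @export
yun_weights <- function(beta_A, beta_B, xbar_A, xbar_B) {
  num_E <- beta_A * (xbar_A - xbar_B)
  num_C <- xbar_B * (beta_A - beta_B)
  D_E <- sum(num_E); D_C <- sum(num_C)
  unstable_E <- abs(D_E) < 1e-12
  unstable_C <- abs(D_C) < 1e-12
  list(w_E = if (unstable_E) numeric(length(num_E)) else num_E / D_E,
       w_C = if (unstable_C) numeric(length(num_C)) else num_C / D_C,
       num_E = num_E, num_C = num_C,
       unstable_E = unstable_E, unstable_C = unstable_C)
}

## The full point-estimate mapping theta = c(beta_A, beta_B) -> outputs.
## Everything downstream (delta method included) flows through this single
## function so estimates and SEs can never disagree about the estimand.
decomp_point <- function(theta, XA, XB, K, norm_map = NULL) {
  bA <- theta[seq_len(K)]
  bB <- theta[K + seq_len(K)]
  pA  <- mean(stats::plogis(drop(XA %*% bA)))
  pBA <- mean(stats::plogis(drop(XB %*% bA)))
  pB  <- mean(stats::plogis(drop(XB %*% bB)))
  R <- pA - pB
  E <- pA - pBA
  C <- pBA - pB
  if (is.null(norm_map)) {
    xbar_A <- colMeans(XA); xbar_B <- colMeans(XB)
    wA <- bA; wB <- bB
  } else {
    xbar_A <- normalized_xbar(colMeans(XA), norm_map$orig_terms, norm_map$spec)
    xbar_B <- normalized_xbar(colMeans(XB), norm_map$orig_terms, norm_map$spec)
    wA <- drop(norm_map$T %*% bA); wB <- drop(norm_map$T %*% bB)
  }
  w <- yun_weights(wA, wB, xbar_A, xbar_B)
  c(R = R, E = E, C = C, E * w$w_E, C * w$w_C)
}

#' Twofold logit decomposition of a binary-outcome gap
#'
#' Decomposes the probability-scale gap in outcome incidence between two
#' groups into an endowment component E (differences in covariate
#' distributions, evaluated at the comparison group's coefficients) and a
#' coefficient component C (differences in covariate effects, evaluated
#' over the reference group's design), with Yun-style detailed per-term
#' attribution. The identities `E + C = R` and `sum(detailed) = aggregate`
#' hold to 1e-10 by construction and are asserted on every run.
#'
#' Standard errors propagate the two coefficient covariances through the
#' full mapping by the delta method (design means treated as fixed); a
#' household-resampling bootstrap is available as a cross-check.
#'
#' @param fit_A,fit_B `che_logit` fits for the comparison group A (default
#'   convention: non-insured) and reference group B (insured). Both must
#'   share an identical term map.
#' @param normalization `"none"` (treatment coding; reference rows carry no
#'   detailed contribution of their own) or `"deviation"` (deviation-from-
#'   mean re-expression; detailed categorical contributions, now one per
#'   level including the reference, are invariant to the reference choice).
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param se_method `"delta"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates (default 500).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return Object of class `mvdecomp`: aggregates `R`, `E`, `C` with SEs,
#'   CIs, p-values and percent-of-gap; `detailed` data frame (term,
#'   variable, level, and per-family estimate/SE/CI/percent/p); group
#'   labels, design means, and instability flags.
#' @references Powers, D.A., Yoshioka, H., Yun, M.-S. (2011) mvdcmp:
#'   Multivariate decomposition for nonlinear response models. The Stata
#'   Journal 11(4), 556-576. Yun, M.-S. (2004) Decomposing differences in
#'   the first moment. Economics Letters 82, 275-280.
#' @export
mvdecomp <- function(fit_A, fit_B, normalization = c("none", "deviation"),
                     conf_level = 0.95, se_method = c("delta", "bootstrap"),
                     boot_reps = 500, boot_seed = NULL) {
  normalization <- match.arg(normalization)
  se_method <- match.arg(se_method)
  stopifnot(inherits(fit_A, "che_logit"), inherits(fit_B, "che_logit"))
  if (!identical(fit_A$terms$column, fit_B$terms$column)) {
    stop("fits have different term maps; build both designs from one spec",
         call. = FALSE)
  }
  XA <- fit_A$X; XB <- fit_B$X
  K <- length(fit_A$beta)
  terms <- fit_A$terms

  norm_map <- NULL
  det_terms <- terms
  det_terms$term <- det_terms$column
  if (normalization == "deviation") {
    spec <- fit_A$spec
    if (is.null(spec)) {
      stop("deviation normalization needs the design spec on the fit; ",
           "use decompose_gap() or fit from a build_design() object",
           call. = FALSE)
    }
    nm <- normalization_transform(terms, spec)
    norm_map <- list(T = nm$T, orig_terms = terms, spec = spec)
    det_terms <- nm$terms
  }

  theta <- c(fit_A$beta, fit_B$beta)
  point <- decomp_point(theta, XA, XB, K, norm_map)
  n_det <- nrow(det_terms)
  est_E <- point[3 + seq_len(n_det)]
  est_C <- point[3 + n_det + seq_len(n_det)]

  w <- yun_weights(
    if (is.null(norm_map)) fit_A$beta else drop(norm_map$T %*% fit_A$beta),
    if (is.null(norm_map)) fit_B$beta else drop(norm_map$T %*% fit_B$beta),
    if (is.null(norm_map)) colMeans(XA) else
      normalized_xbar(colMeans(XA), terms, norm_map$spec),
    if (is.null(norm_map)) colMeans(XB) else
      normalized_xbar(colMeans(XB), terms, norm_map$spec))

  R <- point[["R"]]; E <- point[["E"]]; C <- point[["C"]]
  if (abs(E + C - R) > 1e-10) {
    stop("internal error: twofold identity E + C = R violated", call. = FALSE)
  }
  if (!w$unstable_E && abs(sum(est_E) - E) > 1e-10) {
    stop("internal error: detailed E terms do not sum to E", call. = FALSE)
  }
  if (!w$unstable_C && abs(sum(est_C) - C) > 1e-10) {
    stop("internal error: detailed C terms do not sum to C", call. = FALSE)
  }

  if (se_method == "delta") {
    J <- num_jacobian(function(th) decomp_point(th, XA, XB, K, norm_map), theta)
    V <- block_diag(fit_A$vcov, fit_B$vcov)
    se <- sqrt(pmax(rowSums((J %*% V) * J), 0))
  } else {
    se <- bootstrap_decomposition(fit_A, fit_B, K, norm_map,
                                  reps = boot_reps, seed = boot_seed)
  }
  names(se) <- names(point)
  if (w$unstable_E) se[3 + seq_len(n_det)] <- NA_real_
  if (w$unstable_C) se[3 + n_det + seq_len(n_det)] <- NA_real_

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_lo <- point - z * se
  ci_hi <- point + z * se
  p <- 2 * stats::pnorm(-abs(point / se))
  p[!is.na(se) & se == 0] <- NA_real_  # structurally zero terms
  pct <- if (R != 0) 100 * point / R else rep(NA_real_, length(point))
  if (R == 0) message("R = 0: percent-of-gap columns are undefined")

  idxE <- 3 + seq_len(n_det)
  idxC <- 3 + n_det + seq_len(n_det)
  detailed <- data.frame(
    term = det_terms$term, variable = det_terms$variable,
    level = det_terms$level,
    E = unname(point[idxE]), se_E = unname(se[idxE]),
    ci_lo_E = unname(ci_lo[idxE]), ci_hi_E = unname(ci_hi[idxE]),
    pct_E = unname(pct[idxE]), p_E = unname(p[idxE]),
    C = unname(point[idxC]), se_C = unname(se[idxC]),
    ci_lo_C = unname(ci_lo[idxC]), ci_hi_C = unname(ci_hi[idxC]),
    pct_C = unname(pct[idxC]), p_C = unname(p[idxC]),
    stringsAsFactors = FALSE)

  agg <- function(i) list(estimate = unname(point[i]), se = unname(se[i]),
                          ci = c(unname(ci_lo[i]), unname(ci_hi[i])),
                          p = unname(p[i]), pct = unname(pct[i]))
  structure(list(
    R = agg(1), E = agg(2), C = agg(3),
    detailed = detailed,
    group_A = fit_A$group_label %||% "A",
    group_B = fit_B$group_label %||% "B",
    xbar_A = colMeans(XA), xbar_B = colMeans(XB),
    n_A = fit_A$n, n_B = fit_B$n,
    normalization = normalization, conf_level = conf_level,
    se_method = se_method,
    unstable_E = w$unstable_E, unstable_C = w$unstable_C),
    class = "mvdecomp")
}

## Household-resampling bootstrap within group; returns SEs on the same
## output vector as decomp_point. Replicates where a refit fails
## (separation in a resample) are dropped and counted.
bootstrap_decomposition <- function(fit_A, fit_B, K, norm_map,
                                    reps = 500, seed = NULL) {
  run <- function() {
    out <- matrix(NA_real_, nrow = reps,
                  ncol = length(decomp_point(c(fit_A$beta, fit_B$beta),
                                             fit_A$X, fit_B$X, K, norm_map)))
    fails <- 0L
    for (r in seq_len(reps)) {
      ia <- sample.int(nrow(fit_A$X), replace = TRUE)
      ib <- sample.int(nrow(fit_B$X), replace = TRUE)
      est <- tryCatch({
        fa <- fit_logit(fit_A$X[ia, , drop = FALSE], fit_A$y[ia])
        fb <- fit_logit(fit_B$X[ib, , drop = FALSE], fit_B$y[ib])
        decomp_point(c(fa$beta, fb$beta),
                     fit_A$X[ia, , drop = FALSE], fit_B$X[ib, , drop = FALSE],
                     K, norm_map)
      }, error = function(e) NULL)
      if (is.null(est)) fails <- fails + 1L else out[r, ] <- est
    }
    if (fails > 0.1 * reps) {
      warning(fails, "/", reps, " bootstrap refits failed", call. = FALSE)
    }
    apply(out, 2, stats::sd, na.rm = TRUE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fit both group logits and decompose in one call
#'
#' Convenience wrapper: builds the two treatment-coded designs from one
#' specification (so term maps match and level presence is checked in both
#' groups), fits the group logits, and runs [mvdecomp()].
#'
#' @param records Records with the outcome column and all spec variables.
#' @param spec Design specification; see [default_design_spec()].
#' @param outcome Binary outcome column name (default `"che"`).
#' @param group_var Stratifying variable (default `"insurance"`).
#' @param group_A,group_B Comparison and reference labels; the default
#'   A = non-insured, B = insured makes a positive R mean higher CHE
#'   incidence among the non-insured.
#' @param ... Passed to [mvdecomp()].
#' @return An `mvdecomp` object with the two fits attached as attributes
#'   `fit_A`, `fit_B`.
#' @export
decompose_gap <- function(records, spec = default_design_spec(),
                          outcome = "che", group_var = "insurance",
                          group_A = "non_insured", group_B = "insured", ...) {
  dA <- build_design(records, spec, outcome = outcome, group = group_A,
                     group_var = group_var)
  dB <- build_design(records, spec, outcome = outcome, group = group_B,
                     group_var = group_var)
  fA <- fit_logit(dA, group_label = group_A)
  fB <- fit_logit(dB, group_label = group_B)
  fA$spec <- spec; fB$spec <- spec
  res <- mvdecomp(fA, fB, ...)
  attr(res, "fit_A") <- fA
  attr(res, "fit_B") <- fB
  res
}

#' @export
print.mvdecomp <- function(x, digits = 5, ...) {
  cat("Twofold logit decomposition of", x$group_A, "-", x$group_B,
      "gap\n")
  cat(sprintf("  n_A = %d, n_B = %d, SEs: %s, normalization: %s\n",
              x$n_A, x$n_B, x$se_method, x$normalization))
  fmt <- function(a) sprintf("%9.5f (%.5f, %.5f)  %%%s  p=%.4g",
                             a$estimate, a$ci[1], a$ci[2],
                             ifelse(is.na(a$pct), "NA",
                                    sprintf("%.2f", a$pct)), a$p)
  cat("  Raw gap R:       ", fmt(x$R), "\n")
  cat("  Endowments E:    ", fmt(x$E), "\n")
  cat("  Coefficients C:  ", fmt(x$C), "\n")
  cat("\nDetailed attribution:\n")
  d <- x$detailed
  show <- data.frame(term = d$term,
                     E = round(d$E, digits), pct_E = round(d$pct_E, 2),
                     p_E = signif(d$p_E, 3),
                     C = round(d$C, digits), pct_C = round(d$pct_C, 2),
                     p_C = signif(d$p_C, 3))
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mvdecomp <- function(x, ...) {
  agg <- function(name, a) data.frame(
    term = name, variable = name, level = NA_character_,
    E = NA_real_, se_E = NA_real_, ci_lo_E = NA_real_, ci_hi_E = NA_real_,
    pct_E = NA_real_, p_E = NA_real_,
    C = NA_real_, se_C = NA_real_, ci_lo_C = NA_real_, ci_hi_C = NA_real_,
    pct_C = NA_real_, p_C = NA_real_, stringsAsFactors = FALSE)
  top <- rbind(agg("R", x$R), agg("E", x$E), agg("C", x$C))
  top$E[1:3] <- c(x$R$estimate, x$E$estimate, x$C$estimate)
  top$se_E[1:3] <- c(x$R$se, x$E$se, x$C$se)
  top$ci_lo_E[1:3] <- c(x$R$ci[1], x$E$ci[1], x$C$ci[1])
  top$ci_hi_E[1:3] <- c(x$R$ci[2], x$E$ci[2], x$C$ci[2])
  top$pct_E[1:3] <- c(x$R$pct, x$E$pct, x$C$pct)
  top$p_E[1:3] <- c(x$R$p, x$E$p, x$C$p)
  rbind(top, x$detailed)
}

#' Write decomposition results to CSV and JSON
#'
#' The CSV mirrors the standard published layout: aggregate rows (R, E, C)
#' followed by one detailed row per term with estimate, CI, percent of the
#' gap, and p-value for each family.
#'
#' @param x An `mvdecomp` result.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the result.
#' @export
write_decomposition <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(x), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(R = x$R, E = x$E, C = x$C, detailed = x$detailed,
           group_A = x$group_A, group_B = x$group_B,
           n_A = x$n_A, n_B = x$n_B,
           normalization = x$normalization, se_method = x$se_method,
           conf_level = x$conf_level),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(x)
}
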