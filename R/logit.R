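#' Specify covariates and reference levels for the decomposition design
#'
#' A design specification is a named character vector: names are record
#' variables, values their reference levels (treatment / reference-cell
#' coding; the intercept is always included first). Logical record fields
#' are coded as yes/no factors so a reference of `"yes"` or `"no"` can be
#' named explicitly, and `family_size_cat` is derived from `family_size`
#' on the fly.
#'
#' @return The default full covariate set with the study's reference levels
#'   (male, youngest age band, single, no under-5, small family,
#'   self-employed, poorest, private ownership, chronic condition present,
#'   traditional-medicine use present).
#' @export
default_design_spec <- function() {
  c(head_sex = "male", head_age_group = "<=30", marital_status = "single",
    u5_present = "no", family_size_cat = "<=4", occupation = "self_employed",
    wealth_status = "poorest", ownership = "private",
    chronic_condition = "yes", traditional_medicine = "yes")
}

design_factor_frame <- function(records, spec) {
  vocab <- survey_vocabulary()
  if ("family_size_cat" %in% names(spec) &&
      !"family_size_cat" %in% names(records)) {
    records$family_size_cat <- derive_family_size_cat(records$family_size)
  }
  out <- list()
  for (v in names(spec)) {
    if (!v %in% names(records)) {
      stop("design variable '", v, "' absent from records", call. = FALSE)
    }
    col <- records[[v]]
    if (is.logical(col)) col <- ifelse(col, "yes", "no")
    col <- as.character(col)
    lev <- vocab[[v]] %||% (if (all(col %in% c("yes", "no"))) c("yes", "no")
                            else sort(unique(col)))
    lev <- setdiff(lev, "missing")
    if (!spec[[v]] %in% lev) {
      stop("reference level '", spec[[v]], "' is not a level of '", v, "'",
           call. = FALSE)
    }
    out[[v]] <- factor(col, levels = c(spec[[v]], setdiff(lev, spec[[v]])))
  }
  as.data.frame(out)
}

#' Build a treatment-coded design matrix
#'
#' Constructs the model matrix for the decomposition: intercept first, then
#' `k - 1` reference-cell dummies per categorical variable, in specification
#' order. The term map links every column to its `(variable, level)` pair.
#' Every non-reference level must actually be observed in `records` —
#' an unobserved level would be silently aliased into the reference, so it
#' is an error naming the level instead.
#'
#' @param records Household records (optionally already subset to a group).
#' @param spec Named character vector of covariates and reference levels;
#'   see [default_design_spec()].
#' @param outcome Name of the binary outcome column (default `"che"`);
#'   `NULL` for a design without an outcome (e.g. when simulating).
#' @param group,group_var Optional stratum filter applied before building.
#' @param check_levels Error when a declared level is unobserved (default
#'   `TRUE`; the simulator disables this, since it only needs the coding).
#' @return List of class `che_design`: `X` (numeric matrix), `y` (0/1 vector
#'   or `NULL`), `terms` (data frame: `column`, `variable`, `level`),
#'   `n`, `group`.
#' @export
build_design <- function(records, spec = default_design_spec(),
                         outcome = "che", group = NULL,
                         group_var = "insurance", check_levels = TRUE) {
  if (!is.null(group)) {
    records <- records[records[[group_var]] == group, , drop = FALSE]
    if (!nrow(records)) stop("no records in group '", group, "'", call. = FALSE)
  }
  ff <- design_factor_frame(records, spec)
  for (v in if (check_levels) names(ff) else character()) {
    seen <- unique(as.character(ff[[v]]))
    absent <- setdiff(levels(ff[[v]]), seen)
    if (length(absent)) {
      stop("level(s) of '", v, "' unobserved in ",
           if (is.null(group)) "records" else paste0("group '", group, "'"),
           ": ", paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  X <- stats::model.matrix(~ ., data = ff)
  assign <- attr(X, "assign")
  terms <- data.frame(column = colnames(X),
                      variable = c("(Intercept)", names(ff))[assign + 1L],
                      level = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(terms))[-1]) {
    v <- terms$variable[i]
    terms$level[i] <- sub(paste0("^", v), "", terms$column[i])
  }
  y <- NULL
  if (!is.null(outcome)) {
    if (!outcome %in% names(records)) {
      stop("outcome column '", outcome, "' absent from records", call. = FALSE)
    }
    y <- records[[outcome]]
    if (is.logical(y)) y <- as.integer(y)
    if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  }
  structure(list(X = X[, , drop = FALSE], y = y, terms = terms,
                 n = nrow(X), group = group, spec = spec),
            class = "che_design")
}

#' Fit a logistic regression by Newton-Raphson maximum likelihood
#'
#' Iteratively reweighted least squares with step-halving whenever a full
#' Newton step decreases the log-likelihood; convergence is declared when
#' the gradient's maximum absolute component falls below `tol`. The
#' coefficient covariance is the inverse observed information at the
#' optimum. Fixed tolerances and deterministic iteration make results
#' bit-stable across runs.
#'
#' Perfect separation makes the MLE diverge; it is reported as an error
#' naming the runaway covariate once any `|beta_j| > 15` with a
#' non-vanishing gradient. A singular information matrix is reported as a
#' collinearity error.
#'
#' @param design A `che_design`, or a numeric design matrix.
#' @param y Binary outcome vector (taken from `design` when omitted).
#' @param tol Gradient tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param group_label Optional stratum label stored on the fit.
#' @return Object of class `che_logit`: `beta`, `vcov`, `loglik`, `n`,
#'   `iterations`, `converged`, `group_label`, `terms`, plus the data
#'   (`X`, `y`) for downstream resampling.
#' @export
fit_logit <- function(design, y = NULL, tol = 1e-8, max_iter = 100,
                      group_label = NULL) {
  spec <- NULL
  if (inherits(design, "che_design")) {
    X <- design$X
    y <- y %||% design$y
    terms <- design$terms
    spec <- design$spec
    group_label <- group_label %||% design$group
  } else {
    X <- as.matrix(design)
    terms <- data.frame(column = colnames(X) %||%
                          paste0("x", seq_len(ncol(X))),
                        variable = colnames(X) %||%
                          paste0("x", seq_len(ncol(X))),
                        level = NA_character_)
  }
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than columns", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: all responses identical (no MLE exists)",
         call. = FALSE)
  }

  loglik <- function(eta) sum(y * stats::plogis(eta, log.p = TRUE) +
                                (1 - y) * stats::plogis(-eta, log.p = TRUE))
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (any(abs(beta) > 15)) {
      j <- which.max(abs(beta))
      stop("perfect separation suspected: coefficient for '",
           terms$column[j], "' diverged (|beta| > 15)", call. = FALSE)
    }
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, grad), error = function(e) {
      stop("collinearity: information matrix is singular (",
           conditionMessage(e), ")", call. = FALSE)
    })
    ## step-halving: never accept a likelihood decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(X %*% beta_new)
      ll_new <- loglik(eta_new)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta_new; eta <- eta_new; ll <- ll_new
  }
  if (!converged) {
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    if (max(abs(grad)) < tol) converged <- TRUE
    else warning("fit_logit did not converge in ", max_iter, " iterations",
                 call. = FALSE)
  }
  mu <- stats::plogis(eta)
  H <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(H), error = function(e) {
    stop("collinearity: information matrix is singular at the optimum",
         call. = FALSE)
  })
  vc <- (vc + t(vc)) / 2
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, vcov = vc, loglik = ll, n = n,
                 iterations = iter, converged = converged,
                 group_label = group_label, terms = terms, spec = spec,
                 X = X, y = y),
            class = "che_logit")
}

#' @export
print.che_logit <- function(x, ...) {
  cat("Logistic MLE", if (!is.null(x$group_label))
    paste0(" [", x$group_label, "]"), ": n = ", x$n,
    ", loglik = ", format(x$loglik, digits = 6),
    ", iterations = ", x$iterations,
    if (!x$converged) " (NOT converged)", "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$beta, se = se, z = x$beta / se,
                   row.names = names(x$beta)), digits = 4)
  invisible(x)
}
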