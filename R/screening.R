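#' Cross-tabulate two categorical variables
#'
#' Builds the contingency table of a row variable against a column variable
#' (typically the CHE flag). Logical columns are shown as yes/no; rows
#' carrying the `"missing"` sentinel in either variable are excluded and
#' their count reported in the `"n_missing_excluded"` attribute, so reduced
#' analytic n is always visible.
#'
#' @param records Household records.
#' @param row_variable,column_variable Column names; `column_variable`
#'   defaults to the CHE flag.
#' @return Object of class `contingency_table`: an integer matrix with
#'   attributes `row_variable`, `column_variable`, `n_missing_excluded`.
#' @export
crosstab <- function(records, row_variable, column_variable = "che") {
  vocab <- survey_vocabulary()
  as_cat <- function(v, name) {
    if (is.logical(v)) return(factor(ifelse(v, "yes", "no"),
                                     levels = c("yes", "no")))
    lev <- setdiff(vocab[[name]] %||% sort(unique(as.character(v))), "missing")
    factor(as.character(v), levels = union(lev, unique(as.character(v))))
  }
  rv <- as_cat(records[[row_variable]], row_variable)
  cv <- as_cat(records[[column_variable]], column_variable)
  miss <- rv == "missing" | cv == "missing"
  if (any(miss, na.rm = TRUE)) {
    rv <- factor(as.character(rv[!miss]), levels = setdiff(levels(rv), "missing"))
    cv <- factor(as.character(cv[!miss]), levels = setdiff(levels(cv), "missing"))
  }
  for (v in list(rv, cv)) {
    if (length(v) > 1 && length(unique(as.character(v))) < 2) {
      stop("degenerate table: a variable is constant over the analytic sample",
           call. = FALSE)
    }
  }
  counts <- table(rv, cv, dnn = c(row_variable, column_variable))
  structure(unclass(counts),
            row_variable = row_variable, column_variable = column_variable,
            n_missing_excluded = sum(miss, na.rm = TRUE),
            class = c("contingency_table", "matrix"))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O-E)^2 / E)` with no continuity correction by
#' default (a pinned, documented choice — epidemiologic software defaults
#' vary). A small-cell warning flag is set when any expected count is below
#' 5; a zero row or column margin is an error naming the empty level, since
#' expected counts are then undefined.
#'
#' @param counts A `contingency_table` or plain count matrix.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List of class `chi_square_result`: `statistic`, `df`, `p_value`,
#'   `expected_min`, `warning_small_cells`.
#' @export
chi_square <- function(counts, correct = FALSE) {
  m <- as.matrix(unclass(counts))
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative cell counts", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    empty <- c(rownames(m)[rs == 0], colnames(m)[cs == 0])
    stop("zero margin for level(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 expected_min = min(ct$expected),
                 warning_small_cells = any(ct$expected < 5)),
            class = "chi_square_result")
}

#' Screen explanatory variables by chi-square association
#'
#' Tabulates each candidate against the CHE flag on the analytic sample and
#' keeps those with `p < alpha`, preserving the input order. The full report
#' is returned for audit regardless of selection — the decomposition should
#' never depend on a screening decision that cannot be inspected.
#'
#' @param records Records carrying a logical `che` column.
#' @param candidates Character vector of candidate variable names.
#' @param alpha Significance level (default 0.05, the study convention).
#' @return List with `selected` (names with `p < alpha`) and `report`
#'   (data frame: `variable`, `statistic`, `df`, `p_value`, `n_excluded`,
#'   `small_cells`, `selected`).
#' @export
screen_variables <- function(records, candidates, alpha = 0.05) {
  if (!length(candidates)) stop("no candidate variables", call. = FALSE)
  rows <- lapply(candidates, function(v) {
    tab <- crosstab(records, v)
    cs <- chi_square(tab)
    data.frame(variable = v, statistic = cs$statistic, df = cs$df,
               p_value = cs$p_value,
               n_excluded = attr(tab, "n_missing_excluded"),
               small_cells = cs$warning_small_cells)
  })
  report <- do.call(rbind, rows)
  report$selected <- report$p_value < alpha
  list(selected = report$variable[report$selected], report = report)
}
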