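#' Single-population-proportion sample size
#'
#' `n = z^2 p (1 - p) / d^2`, truncated to an integer, then inflated for
#' non-response (rounded up) and multiplied by the design effect. This
#' reproduces the arithmetic chain conventionally printed in field survey
#' protocols (base truncated, the non-response step rounded up), rather than
#' an idealized ceiling-everywhere convention; the intermediate values are
#' attached as attributes.
#'
#' @param p Expected proportion, in (0, 1).
#' @param d Absolute precision (margin of error), > 0.
#' @param z Normal quantile for the confidence level (default 1.96).
#' @param nonresponse Anticipated non-response fraction (default 0).
#' @param design_effect Design-effect multiplier (default 1).
#' @return Integer sample size, with attributes `base` and
#'   `with_nonresponse`.
#' @examples
#' sample_size(0.5, 0.05)                       # 384
#' sample_size(0.5, 0.05, nonresponse = 0.10, design_effect = 2)  # 846
#' @export
sample_size <- function(p, d, z = 1.96, nonresponse = 0, design_effect = 1) {
  stopifnot(p > 0, p < 1, d > 0, nonresponse >= 0, design_effect >= 1)
  base <- trunc(z^2 * p * (1 - p) / d^2)
  with_nr <- ceiling(base * (1 + nonresponse))
  out <- as.integer(with_nr * design_effect)
  attr(out, "base") <- as.integer(base)
  attr(out, "with_nonresponse") <- as.integer(with_nr)
  out
}

#' Survey response rate
#'
#' @param achieved Households with completed interviews.
#' @param designed Designed sample size.
#' @return Response rate in percent.
#' @export
response_rate <- function(achieved, designed) 100 * achieved / designed

#' Frequency/percent descriptive table
#'
#' One row per category of each requested variable, with count and percent
#' of the analytic n (percent to 2 dp, the reporting convention of survey
#' tables). Logical variables are shown as yes/no.
#'
#' @param records Household records.
#' @param variables Character vector of column names.
#' @return Data frame: `variable`, `category`, `count`, `percent`.
#' @export
descriptive_table <- function(records, variables) {
  n <- nrow(records)
  rows <- lapply(variables, function(v) {
    col <- records[[v]]
    if (is.null(col)) stop("no column '", v, "'", call. = FALSE)
    if (is.logical(col)) col <- ifelse(col, "yes", "no")
    tab <- table(as.character(col))
    data.frame(variable = v, category = names(tab),
               count = as.integer(tab),
               percent = fmt_pct(as.integer(tab) / n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expand an aggregated count table to one row per unit
#'
#' Inverse of tabulation: repeats each combination of the non-`count`
#' columns `count` times. Used to rebuild record-level data from published
#' marginal or cross-tabulated counts.
#'
#' @param counts Data frame whose integer `count` column gives repetitions.
#' @return Data frame of expanded rows (without the `count` column).
#' @export
expand_counts <- function(counts) {
  stopifnot("count" %in% names(counts))
  out <- counts[rep(seq_len(nrow(counts)), counts$count),
                setdiff(names(counts), "count"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Config-driven orchestration from input records (a survey CSV or a
#' synthetic configuration) through CHE measurement, wealth-index
#' construction, chi-square screening, and the twofold decomposition.
#' Every stage's output is written under `output_dir` along with a
#' reproducibility manifest (config hash, seed, package version, row count
#' at each stage).
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `input` (either `survey` — a CSV path — or `synthetic` — a list of
#'   [synthetic_config()] arguments plus optional `mode`
#'   `"outcome"`/`"expenditure"`); `threshold` (default 0.10);
#'   `denominator_kind`; `covariates` (named vector of reference levels,
#'   default [default_design_spec()]); `alpha` (default 0.05);
#'   `missing_mode` (`"listwise"` or `"drop_variable"`, for the
#'   referral-history sentinel; default `"drop_variable"`); `se_method`;
#'   `normalization`; `seed`.
#' @param output_dir Output directory (created if needed).
#' @return The manifest list, invisibly; artifact files on disk.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$input) ||
      sum(c("survey", "synthetic") %in% names(config$input)) != 1L) {
    stop("config must name exactly one input source ('survey' or 'synthetic')",
         call. = FALSE)
  }
  threshold <- config$threshold %||% 0.10
  denominator_kind <- config$denominator_kind %||% "total"
  covariates <- unlist(config$covariates) %||% default_design_spec()
  alpha <- config$alpha %||% 0.05
  missing_mode <- config$missing_mode %||% "drop_variable"
  se_method <- config$se_method %||% "delta"
  normalization <- config$normalization %||% "none"
  seed <- config$seed %||% 1L

  counts <- list()
  stage_files <- character()
  emit <- function(name) stage_files <<- c(stage_files, name)

  ## stage 1: input
  synthetic_mode <- NULL
  if (!is.null(config$input$survey)) {
    records <- read_survey(config$input$survey, schema = config$input$schema)
  } else {
    syn <- config$input$synthetic
    synthetic_mode <- syn$mode %||% "outcome"
    syn$mode <- NULL
    syn$seed <- syn$seed %||% seed
    cfg <- do.call(synthetic_config, syn)
    gen <- if (synthetic_mode == "expenditure") generate_expenditure_level(cfg)
           else generate_outcome_level(cfg)
    records <- gen$records
  }
  counts$input <- nrow(records)

  ## stage 2: CHE measurement (skip when the flag was generated directly)
  if (!"che" %in% names(records)) {
    records <- che_flag(records, threshold = threshold,
                        denominator_kind = denominator_kind)
  }
  che_cols <- intersect(c("household_id", "insurance", "health_expenditure",
                          "denominator_expenditure", "che_share", "che"),
                        names(records))
  utils::write.csv(records[che_cols], file.path(output_dir, "che_table.csv"),
                   row.names = FALSE)
  emit("che_table.csv")
  counts$che <- nrow(records)

  ## stage 3: wealth index (only when asset columns are present)
  if (any(grepl("^asset_", names(records)))) {
    wi <- build_wealth_index(records)
    records$wealth_status <- as.character(wi$quintile)
    write_wealth_model(wi$model, file.path(output_dir, "wealth_model.json"))
  } else {
    jsonlite::write_json(list(note = paste(
      "no asset columns in input; wealth_status taken from records")),
      file.path(output_dir, "wealth_model.json"), auto_unbox = TRUE)
  }
  emit("wealth_model.json")

  ## missing-data policy for the referral-history sentinel
  candidates <- names(covariates)
  if ("referral_history" %in% names(records)) {
    n_missing <- sum(records$referral_history == "missing")
    if (missing_mode == "listwise" && n_missing > 0) {
      records <- records[records$referral_history != "missing", , drop = FALSE]
    } else if (missing_mode == "drop_variable") {
      candidates <- setdiff(candidates, "referral_history")
    }
  }
  counts$analytic <- nrow(records)

  ## stage 4: screening
  if ("family_size_cat" %in% candidates &&
      !"family_size_cat" %in% names(records)) {
    records$family_size_cat <-
      as.character(derive_family_size_cat(records$family_size))
  }
  scr <- screen_variables(records, candidates, alpha = alpha)
  utils::write.csv(scr$report, file.path(output_dir, "screening.csv"),
                   row.names = FALSE)
  emit("screening.csv")

  ## stage 5: decomposition over the screened covariate set
  spec <- covariates[scr$selected]
  if (!length(spec)) stop("no covariates survived screening", call. = FALSE)
  res <- decompose_gap(records, spec, se_method = se_method,
                       normalization = normalization,
                       boot_seed = seed)
  write_decomposition(res, file.path(output_dir, "decomposition.csv"),
                      file.path(output_dir, "decomposition.json"))
  emit("decomposition.csv")

  cfg_canon <- config
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(cfg_canon, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("chedecomp")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    threshold = threshold,
    denominator_kind = denominator_kind,
    missing_mode = missing_mode,
    synthetic_mode = synthetic_mode,
    stage_outputs = stage_files,
    row_counts = counts,
    screened_in = scr$selected,
    screened_out = setdiff(candidates, scr$selected),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
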