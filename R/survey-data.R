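#' Category vocabulary for household survey records
#'
#' The coded-category vocabulary shared by every pipeline stage. Categorical
#' fields read from disk must use exactly these labels; anything else is a
#' schema error, never a silent recode. `referral_history` is the only field
#' permitted to be missing, and missingness is encoded by the explicit
#' sentinel label `"missing"` (never an empty cell) so that listwise behavior
#' stays auditable.
#'
#' @return Named list of allowed labels per categorical field.
#' @export
survey_vocabulary <- function() {
  list(
    head_sex          = c("male", "female"),
    head_age_group    = c("<=30", "31-45", "46-60", ">60"),
    marital_status    = c("single", "married", "separated", "divorced", "widowed"),
    occupation        = c("self_employed", "government", "private_sector"),
    ownership         = c("private", "rent"),
    insurance         = c("insured", "non_insured"),
    family_size_cat   = c("<=4", ">4"),
    wealth_status     = c("poorest", "poorer", "middle", "richer", "richest"),
    referral_history  = c("yes", "no", "missing")
  )
}

## Insurance code map per the study convention: insured = 0, non-insured = 1.
## Numeric codes appear only inside design matrices; records keep labels.
insurance_codes <- function() c(insured = 0L, non_insured = 1L)

survey_categorical_fields <- function() {
  c("head_sex", "marital_status", "occupation", "ownership", "insurance",
    "referral_history")
}

survey_logical_fields <- function() {
  c("u5_present", "chronic_condition", "traditional_medicine")
}

survey_numeric_fields <- function() {
  c("head_age", "family_size", "food", "nonfood_nonhealth", "direct_medical",
    "direct_nonmedical", "lost_days", "daily_valuation")
}

survey_mandatory_fields <- function() {
  c("household_id", "kebele", survey_categorical_fields(),
    survey_logical_fields(), survey_numeric_fields())
}

#' Derive the age band of a household head
#'
#' Maps age in completed years onto the four analysis bands
#' `<=30`, `31-45`, `46-60`, `>60` (upper bound inclusive in each closed
#' band). Household heads are adults; ages below 18 are a domain error.
#'
#' @param age Integer vector of ages in years, all `>= 18`.
#' @return Factor with levels `<=30`, `31-45`, `46-60`, `>60`.
#' @examples
#' derive_age_group(c(30, 46, 61))
#' @export
derive_age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("head_age must be >= 18 years (household heads are adults)",
         call. = FALSE)
  }
  bands <- survey_vocabulary()$head_age_group
  factor(bands[findInterval(age, c(18, 31, 46, 61))], levels = bands)
}

#' Derive the family-size category
#'
#' @param family_size Integer vector, all `>= 1`.
#' @return Factor with levels `<=4`, `>4`.
#' @export
derive_family_size_cat <- function(family_size) {
  factor(ifelse(family_size <= 4, "<=4", ">4"),
         levels = survey_vocabulary()$family_size_cat)
}

#' Validate household survey records
#'
#' Enforces the data model shared by all stages: mandatory columns present,
#' categorical labels inside [survey_vocabulary()], logical fields logical,
#' and the row-level invariants (adult head, `family_size >= 1`, all
#' expenditure components finite and `>= 0`, `head_age_group` consistent with
#' `head_age`). Structural problems (missing columns, unknown labels,
#' unparseable numbers, `NA` anywhere) are hard errors; rows violating the
#' numeric invariants are rejected individually with row-indexed diagnostics.
#'
#' @param records Data frame of candidate household records.
#' @return The validated records (invalid rows dropped, `head_age_group`
#'   filled in), with attribute `"rejected"` — a data frame of
#'   `(row, reason)` diagnostics for every dropped row.
#' @export
validate_households <- function(records) {
  stopifnot(is.data.frame(records))
  vocab <- survey_vocabulary()

  missing_cols <- setdiff(survey_mandatory_fields(), names(records))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  for (f in survey_categorical_fields()) {
    v <- as.character(records[[f]])
    if (anyNA(v) || any(v == "")) {
      stop("missing values in '", f, "' are not permitted",
           if (f == "referral_history") " (use the sentinel label 'missing')",
           call. = FALSE)
    }
    bad <- setdiff(unique(v), vocab[[f]])
    if (length(bad)) {
      stop("unknown label(s) in '", f, "': ",
           paste(sQuote(bad), collapse = ", "),
           "; allowed: ", paste(vocab[[f]], collapse = ", "), call. = FALSE)
    }
    records[[f]] <- v
  }

  for (f in survey_logical_fields()) {
    v <- records[[f]]
    if (is.character(v)) {
      v <- tolower(v)
      ok <- v %in% c("true", "false", "yes", "no")
      if (!all(ok)) {
        stop("column '", f, "' must be logical; offending row(s): ",
             paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
      }
      v <- v %in% c("true", "yes")
    }
    if (!is.logical(v) || anyNA(v)) {
      stop("column '", f, "' must be logical with no missing values",
           call. = FALSE)
    }
    records[[f]] <- v
  }

  for (f in survey_numeric_fields()) {
    v <- records[[f]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("parse error: non-numeric '", f, "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      v <- num
    }
    if (anyNA(v)) {
      stop("missing values in numeric column '", f, "' are not permitted",
           call. = FALSE)
    }
    records[[f]] <- as.numeric(v)
  }

  asset_cols <- grep("^asset_", names(records), value = TRUE)
  for (f in asset_cols) {
    v <- records[[f]]
    if (is.character(v)) v <- tolower(v) %in% c("true", "yes", "1")
    if (is.numeric(v)) v <- v != 0
    if (!is.logical(v) || anyNA(v)) {
      stop("asset column '", f, "' must be logical with no missing values",
           call. = FALSE)
    }
    records[[f]] <- v
  }

  ## row-level invariants -> reject rows with diagnostics
  reject <- list()
  flag <- function(rows, reason) {
    if (length(rows)) reject[[length(reject) + 1L]] <<-
        data.frame(row = rows, reason = reason)
  }
  flag(which(records$head_age < 18), "head_age < 18")
  flag(which(records$family_size < 1), "family_size < 1")
  for (f in c("food", "nonfood_nonhealth", "direct_medical",
              "direct_nonmedical", "lost_days", "daily_valuation")) {
    flag(which(records[[f]] < 0 | !is.finite(records[[f]])),
         paste0(f, " negative or non-finite"))
  }
  if ("head_age_group" %in% names(records)) {
    ok_rows <- records$head_age >= 18
    derived <- rep(NA_character_, nrow(records))
    derived[ok_rows] <- as.character(derive_age_group(records$head_age[ok_rows]))
    flag(which(ok_rows & as.character(records$head_age_group) != derived),
         "head_age_group inconsistent with head_age")
  }

  rejected <- if (length(reject)) {
    r <- do.call(rbind, reject)
    stats::aggregate(reason ~ row, data = r,
                     FUN = function(x) paste(x, collapse = "; "))
  } else {
    data.frame(row = integer(), reason = character())
  }

  if (nrow(rejected)) {
    records <- records[-rejected$row, , drop = FALSE]
    warning(nrow(rejected), " row(s) rejected: ",
            paste(sprintf("row %d (%s)", utils::head(rejected$row, 5),
                          utils::head(rejected$reason, 5)), collapse = "; "),
            if (nrow(rejected) > 5) " ...", call. = FALSE)
  }
  records$head_age_group <- as.character(derive_age_group(records$head_age))
  rownames(records) <- NULL
  attr(records, "rejected") <- rejected
  records
}

canonical_column_order <- function(records) {
  asset_cols <- sort(grep("^asset_", names(records), value = TRUE))
  lead <- c("household_id", "kebele", "head_sex", "head_age", "head_age_group",
            "marital_status", "occupation", "family_size", "u5_present",
            "ownership", "insurance", "chronic_condition",
            "traditional_medicine", "referral_history")
  money <- c("food", "nonfood_nonhealth", "direct_medical",
             "direct_nonmedical", "lost_days", "daily_valuation")
  extra <- setdiff(names(records), c(lead, money, asset_cols))
  records[, c(lead, extra, asset_cols, money)[c(lead, extra, asset_cols, money)
                                              %in% names(records)],
          drop = FALSE]
}

#' Read household survey records from a delimited file
#'
#' Reads a UTF-8 CSV with header, optionally applies a schema mapping
#' (renaming file columns to canonical fields and recoding file labels to the
#' canonical vocabulary), then validates via [validate_households()]. All
#' cells are first read as text so that unparseable numbers are reported with
#' their row number rather than silently becoming `NA`.
#'
#' @param path Path to a CSV file with header.
#' @param schema Optional schema: a list with elements `columns` (named
#'   character vector, canonical field -> file column name) and `labels`
#'   (named list; per field, a named character vector mapping file labels to
#'   vocabulary labels), or a path to a YAML/JSON document with that shape.
#' @return Validated data frame of household records, with the `"rejected"`
#'   diagnostics attribute from [validate_households()].
#' @seealso [write_survey()]
#' @export
read_survey <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    if (is.character(schema)) schema <- read_schema(schema)
    if (!is.null(schema$columns)) {
      cols <- unlist(schema$columns)
      missing_src <- setdiff(unname(cols), names(df))
      if (length(missing_src)) {
        stop("schema error: mapped column(s) absent from file: ",
             paste(missing_src, collapse = ", "), call. = FALSE)
      }
      idx <- match(unname(cols), names(df))
      names(df)[idx] <- names(cols)
    }
    if (!is.null(schema$labels)) {
      for (f in names(schema$labels)) {
        map <- unlist(schema$labels[[f]])
        hit <- df[[f]] %in% names(map)
        df[[f]][hit] <- unname(map[df[[f]][hit]])
      }
    }
  }
  validate_households(df)
}

#' Read a schema mapping document
#'
#' @param path YAML (or JSON) schema document with optional `columns` and
#'   `labels` elements; see [read_survey()].
#' @return Schema list.
#' @export
read_schema <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Write household survey records to a delimited file
#'
#' Emits UTF-8 CSV with header, readable losslessly by [read_survey()]
#' (category labels are stored as human-readable strings; logicals as
#' TRUE/FALSE). An empty collection yields a header-only file.
#'
#' @param records Validated household records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  records <- canonical_column_order(records)
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write survey file '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
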