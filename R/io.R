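#' @keywords internal
cohort_columns <- function() {
  c("id", "age", "sex", "height", "body_mass", "sbp", "dbp",
    "ao_diastolic_diameter", "ao_systolic_diameter",
    "eat_thickness", "eat_volume")
}

#' Validate a cohort table
#'
#' Checks the schema and the per-record physical invariants: positive
#' height and mass, sbp > dbp > 0, systolic >= diastolic aortic diameter
#' > 0, non-negative EAT measures, sex in {male, female}. Violations are a
#' data error and are never silently clamped; every offending row is named.
#'
#' @param cohort Data frame to validate.
#' @return The cohort, invisibly, if valid; otherwise an error listing each
#'   invalid row.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  num_cols <- setdiff(cohort_columns(), c("id", "sex"))
  issues <- character(0)
  for (col in num_cols) {
    bad <- which(!is.finite(as.numeric(cohort[[col]])))
    if (length(bad)) {
      issues <- c(issues, paste0("row ", bad, ": non-numeric ", col))
    }
  }
  if (!length(issues)) {
    chk <- function(cond, msg) {
      bad <- which(!cond)
      if (length(bad)) paste0("row ", bad, ": ", msg) else character(0)
    }
    issues <- c(issues,
      chk(cohort$height > 0, "height must be > 0"),
      chk(cohort$body_mass > 0, "body_mass must be > 0"),
      chk(cohort$dbp > 0, "dbp must be > 0"),
      chk(cohort$sbp > cohort$dbp, "sbp must exceed dbp"),
      chk(cohort$ao_diastolic_diameter > 0,
          "ao_diastolic_diameter must be > 0"),
      chk(cohort$ao_systolic_diameter >= cohort$ao_diastolic_diameter,
          "ao_systolic_diameter below ao_diastolic_diameter"),
      chk(cohort$eat_thickness >= 0, "eat_thickness must be >= 0"),
      chk(cohort$eat_volume >= 0, "eat_volume must be >= 0"),
      chk(cohort$sex %in% c("male", "female"), "sex must be male or female"))
  }
  if (length(issues)) {
    stop("invalid cohort record(s):\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a per-patient cohort table (UTF-8, decimal point, header row with
#' the canonical column names) and validates every record. By default any
#' invalid row aborts the read; with `skip_invalid = TRUE` offending rows
#' are dropped with a warning naming them.
#'
#' @param path Path to the CSV file.
#' @param skip_invalid Drop invalid rows instead of erroring.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[cohort_columns()]
  df$id <- as.character(df$id)
  if (!skip_invalid) {
    validate_cohort(df)
    return(df)
  }
  keep <- vapply(seq_len(nrow(df)), function(i) {
    ok <- TRUE
    tryCatch(validate_cohort(df[i, , drop = FALSE]),
             error = function(e) ok <<- FALSE)
    ok
  }, logical(1))
  if (any(!keep)) {
    warning("dropped ", sum(!keep), " invalid row(s): ",
            paste(which(!keep), collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) stop("no valid rows in ", path, call. = FALSE)
  df[keep, , drop = FALSE]
}

#' Write a cohort (or derived) table as CSV
#'
#' Numbers are written unrounded so that a write/read round trip is
#' lossless to floating-point printing precision.
#'
#' @param cohort Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(format(cohort, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
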