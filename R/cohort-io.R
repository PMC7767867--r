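COHORT_COLUMNS <- c("infant_id", "ga_weeks", "birth_weight_g", "length_cm",
                    "head_circ_cm", "igf1_w3", "igf1_w5", "sepsis_w3",
                    "rop_grade")
# risk_stratum is the generator's latent stratum; carried when present,
# never required.
COHORT_OPTIONAL_COLUMNS <- c("risk_stratum", "unstable")

#' Validate infant records
#'
#' Enforces the `InfantRecord` invariants on a cohort data frame: positive
#' gestational age, birth weight and IGF1 values, 0/1 sepsis flag and a known
#' ROP grade. Errors name the first offending row.
#'
#' @param cohort Data frame of infant records.
#' @return `cohort`, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(cohort), c(COHORT_COLUMNS, COHORT_OPTIONAL_COLUMNS))
  if (length(unknown) > 0) {
    stop("cohort schema error: unknown column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0) return(invisible(cohort))
  if (anyDuplicated(cohort$infant_id)) {
    stop("cohort validation error: duplicated infant_id at row ",
         anyDuplicated(cohort$infant_id), call. = FALSE)
  }
  checks <- list(
    ga_weeks = !is.na(cohort$ga_weeks) & cohort$ga_weeks > 0,
    birth_weight_g = !is.na(cohort$birth_weight_g) & cohort$birth_weight_g > 0,
    igf1_w3 = !is.na(cohort$igf1_w3) & cohort$igf1_w3 > 0,
    igf1_w5 = is.na(cohort$igf1_w5) | cohort$igf1_w5 > 0,
    sepsis_w3 = cohort$sepsis_w3 %in% c(0L, 1L),
    rop_grade = cohort$rop_grade %in% ROP_GRADES
  )
  for (field in names(checks)) {
    bad <- which(!checks[[field]])
    if (length(bad) > 0) {
      stop(sprintf("cohort validation error: invalid %s at row %d",
                   field, bad[1]), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' Comma-separated UTF-8 with the fixed header
#' `infant_id,ga_weeks,birth_weight_g,length_cm,head_circ_cm,igf1_w3,igf1_w5,sepsis_w3,rop_grade`
#' (plus `risk_stratum` when the generator's latent stratum is present);
#' booleans as 0/1, missing optional values as empty fields. Numeric fields
#' round-trip at full double precision.
#'
#' @param cohort Cohort data frame (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  cols <- c(COHORT_COLUMNS, intersect(COHORT_OPTIONAL_COLUMNS, names(cohort)))
  out <- cohort[, cols, drop = FALSE]
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
      out[[col]][out[[col]] %in% c("NA", "nan")] <- NA_character_
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x))` reproduces all
#' fields to full precision. Unknown or missing mandatory columns raise a
#' schema error; rows violating record invariants raise a validation error
#' naming the row.
#'
#' @param path CSV file path.
#' @return A `rop_cohort` tibble.
#' @export
read_cohort <- function(path) {
  header <- gsub('"', "", strsplit(readLines(path, n = 1L), ",",
                                   fixed = TRUE)[[1]])
  missing_cols <- setdiff(COHORT_COLUMNS, header)
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # read everything as character, then convert numerics via strtod so that
  # %.17g output round-trips bit-exactly (readr's fast parser can be 1 ulp
  # off at full precision) and parse failures carry a line number
  cohort <- readr::read_csv(path,
                            col_types = readr::cols(
                              .default = readr::col_character()),
                            na = "", progress = FALSE)
  numeric_cols <- c("ga_weeks", "birth_weight_g", "length_cm",
                    "head_circ_cm", "igf1_w3", "igf1_w5")
  integer_cols <- c("sepsis_w3", "unstable")
  for (col in intersect(c(numeric_cols, integer_cols), names(cohort))) {
    raw <- cohort[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("cohort parse error at line %d: cannot parse %s value '%s'",
                   bad[1] + 1L, col, raw[bad[1]]), call. = FALSE)
    }
    cohort[[col]] <- if (col %in% integer_cols) as.integer(parsed) else parsed
  }
  validate_cohort(cohort)
  class(cohort) <- c("rop_cohort", class(cohort))
  cohort
}
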