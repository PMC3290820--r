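#' @keywords internal
"_PACKAGE"

#' CBC marker names used by the default candidate algebra
#'
#' The 12 first-cycle complete-blood-count markers, in the fixed canonical
#' order used everywhere in this package: white-cell count (WBC), hemoglobin
#' (HGB), platelets (PLT) and absolute neutrophil count (ANC), each measured
#' on day 0 (baseline), day 7 (nadir region) and day 28 (recovery) of the
#' first chemotherapy cycle. `cbc_marker_columns()` gives the matching CSV
#' column names, `cbc_marker_names()` the display names used in term labels
#' such as `"PLT28*ANC28"`.
#'
#' @return Character vector of length 12.
#' @export
cbc_marker_names <- function() {
  paste0(rep(c("WBC", "HGB", "PLT", "ANC"), times = 3),
         rep(c("0", "7", "28"), each = 4))
}

#' @rdname cbc_marker_names
#' @export
cbc_marker_columns <- function() {
  paste0(rep(c("wbc", "hgb", "plt", "anc"), times = 3),
         rep(c("_d0", "_d7", "_d28"), each = 4))
}

# Optional demographics accepted in patient CSVs.
demographic_columns <- function() c("age", "height_cm", "weight_kg", "bmi")

#' Assemble a validated patient table
#'
#' Builds the canonical patient data frame used throughout the pipeline:
#' one row per patient, a `patient_id` column, the 12 CBC marker columns
#' (see [cbc_marker_columns()]), optional demographics, and an optional
#' `risk_label` column coded +1 (high risk) / -1 (low risk).
#'
#' Records with any missing or negative CBC value are rejected: the method
#' requires complete counts on the vital days, so incomplete records are
#' dropped with a warning naming each patient and marker rather than
#' imputed.
#'
#' @param df data.frame with at least `patient_id` and the 12 CBC columns.
#' @return data.frame of class `fos3nn_patients` containing only valid rows.
#' @export
as_patients <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"patient_id" %in% names(df)) stop("patient CSV must have a 'patient_id' column")
  need <- cbc_marker_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("patient table is missing CBC columns: ", paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id values")
  for (col in need) df[[col]] <- as.numeric(df[[col]])
  bad <- rep(FALSE, nrow(df))
  for (col in need) {
    nv <- !is.finite(df[[col]]) | df[[col]] < 0
    if (any(nv)) {
      warning(sprintf("rejecting patient(s) %s: missing/invalid %s",
                      paste(df$patient_id[nv], collapse = ", "), col),
              call. = FALSE)
      bad <- bad | nv
    }
  }
  df <- df[!bad, , drop = FALSE]
  if ("risk_label" %in% names(df)) {
    df$risk_label <- parse_risk_label(df$risk_label)
  }
  class(df) <- c("fos3nn_patients", "data.frame")
  df
}

# Accepts +1/-1, "high"/"low" (case-insensitive); NA passes through.
parse_risk_label <- function(x) {
  out <- rep(NA_real_, length(x))
  chr <- tolower(trimws(as.character(x)))
  out[chr %in% c("1", "+1", "high")] <- 1
  out[chr %in% c("-1", "low")] <- -1
  unknown <- !is.na(x) & chr != "" & chr != "na" & is.na(out)
  if (any(unknown)) {
    stop("unparseable risk_label value(s): ", paste(unique(x[unknown]), collapse = ", "))
  }
  out
}

#' Read / write patient CSV files
#'
#' The patient CSV has one row per patient with columns `patient_id`,
#' optional demographics (`age`, `height_cm`, `weight_kg`, `bmi`), the 12
#' CBC marker columns and an optional `risk_label` column (`+1`/`-1` or
#' `high`/`low`). Rows with incomplete CBC data are rejected with a warning.
#'
#' @param path file path.
#' @param patients a patient data frame (see [as_patients()]).
#' @return `read_patients()` returns a validated `fos3nn_patients` frame.
#' @export
read_patients <- function(path) {
  as_patients(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_patients
#' @export
write_patients <- function(patients, path) {
  atomic_write_csv(as.data.frame(patients), path)
}

#' Extract the 12-column raw marker matrix from a patient table
#'
#' @param patients validated patient table.
#' @return numeric matrix, rows named by `patient_id`, columns by
#'   [cbc_marker_names()].
#' @export
marker_matrix <- function(patients) {
  m <- as.matrix(as.data.frame(patients)[, cbc_marker_columns()])
  dimnames(m) <- list(patients$patient_id, cbc_marker_names())
  m
}

# write-then-rename so a failed run never leaves a truncated file
atomic_write_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

atomic_write_json <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  # I(17) = 17 significant digits, enough to round-trip any double exactly
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = I(17), null = "null")
  file.rename(tmp, path)
  invisible(path)
}
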