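#' Load and validate a cohort table
#'
#' Reads a comma-separated cohort file (UTF-8, '.' decimal, empty cells for
#' missing values), types the columns, fills derivable columns when absent,
#' and enforces range invariants. One row per subject.
#'
#' Derived columns (only computed when missing from the file):
#' \describe{
#'   \item{`fazekas_total`}{`fazekas_pwmh + fazekas_dwmh`.}
#'   \item{`group`}{`HC` for Fazekas total 0, `mild` for 1-3, `severe` for
#'     4-6.}
#'   \item{`bmi`}{`weight / height^2` (kg, m) when both are present.}
#'   \item{`chp_latvent`}{`chp_volume / latvent_volume`.}
#'   \item{`chp_icv`}{`chp_volume / icv`.}
#'   \item{`total_wmh_volume`}{`pwmh_volume + dwmh_volume`.}
#'   \item{`alps_avg`}{`(alps_left + alps_right) / 2`.}
#' }
#'
#' @param path CSV file path.
#' @return A `data.frame` with class `cohort_table`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  as_cohort_table(df)
}

#' Coerce a data frame to a validated cohort table
#'
#' Applies the same typing, derivation and validation rules as
#' [load_cohort()].
#'
#' @param df A data frame with at least a `subject_id` column.
#' @return A `cohort_table` data frame.
#' @export
as_cohort_table <- function(df) {
  if (!"subject_id" %in% names(df)) stop("cohort table needs a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  }
  if ("sex" %in% names(df)) {
    df$sex <- factor(as.character(df$sex), levels = c("M", "F"))
  }
  if ("hypertension" %in% names(df)) {
    df$hypertension <- as.logical(df$hypertension)
  }

  chk_range <- function(col, lo, hi) {
    if (col %in% names(df)) {
      v <- df[[col]]
      bad <- !is.na(v) & (v < lo | v > hi)
      if (any(bad)) {
        stop(col, " outside [", lo, ", ", hi, "] for subject(s): ",
             paste(df$subject_id[bad], collapse = ", "))
      }
    }
  }
  chk_range("fazekas_pwmh", 0, 3)
  chk_range("fazekas_dwmh", 0, 3)
  chk_range("fazekas_total", 0, 6)
  chk_range("mmse", 0, 30)
  chk_range("moca", 0, 30)
  for (col in intersect(c("pwmh_volume", "dwmh_volume", "total_wmh_volume",
                          "chp_volume", "latvent_volume", "icv"), names(df))) {
    chk_range(col, 0, Inf)
  }

  has <- function(...) all(c(...) %in% names(df))
  if (!has("fazekas_total") && has("fazekas_pwmh", "fazekas_dwmh")) {
    df$fazekas_total <- df$fazekas_pwmh + df$fazekas_dwmh
  }
  if (!has("group") && has("fazekas_total")) {
    df$group <- fazekas_group(total = df$fazekas_total)
  } else if (has("group")) {
    df$group <- factor(as.character(df$group), levels = c("HC", "mild", "severe"))
  }
  if (!has("bmi") && has("weight", "height")) {
    df$bmi <- df$weight / df$height^2
  }
  if (!has("total_wmh_volume") && has("pwmh_volume", "dwmh_volume")) {
    df$total_wmh_volume <- df$pwmh_volume + df$dwmh_volume
  }
  if (!has("chp_latvent") && has("chp_volume", "latvent_volume")) {
    df$chp_latvent <- df$chp_volume / df$latvent_volume
  }
  if (!has("chp_icv") && has("chp_volume", "icv")) {
    df$chp_icv <- df$chp_volume / df$icv
  }
  if (!has("alps_avg") && has("alps_left", "alps_right")) {
    df$alps_avg <- (df$alps_left + df$alps_right) / 2
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
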