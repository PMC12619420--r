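.required_encounter_cols <- c("encounter_id", "t0", "treatment_received",
                              "imv", "mortality_or_hospice")
.required_obs_cols <- c("encounter_id", "variable", "hours_before_t0", "value")

#' Write a cohort to disk
#'
#' Serialises a cohort as two UTF-8 CSV files in a directory:
#' \code{encounters.csv} (one row per encounter, including the
#' \code{oracle_}-prefixed ground-truth columns) and
#' \code{observations.csv} (long format). Missing values are written as
#' empty fields.
#'
#' @param cohort an \code{icu_cohort}.
#' @param path directory to create/write into.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "icu_cohort")) stopf("cohort must be an icu_cohort")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$encounters, file.path(path, "encounters.csv"),
                     na = "")
  data.table::fwrite(cohort$observations, file.path(path, "observations.csv"),
                     na = "")
  invisible(path)
}

#' Read a cohort from disk
#'
#' Inverse of \code{\link{write_cohort}}; validates the schema and reports
#' the offending column (and file) when it is malformed.
#'
#' @param path directory written by \code{\link{write_cohort}}.
#' @return an \code{icu_cohort} (with a \code{NULL} config).
#' @export
read_cohort <- function(path) {
  ef <- file.path(path, "encounters.csv")
  of <- file.path(path, "observations.csv")
  if (!file.exists(ef)) stopf("missing file: %s", ef)
  if (!file.exists(of)) stopf("missing file: %s", of)
  enc <- as.data.frame(data.table::fread(ef, na.strings = ""))
  miss <- setdiff(.required_encounter_cols, names(enc))
  if (length(miss))
    stopf("encounters.csv: missing required column(s): %s",
          paste(miss, collapse = ", "))
  bad_tr <- which(!enc$treatment_received %in% c("NIV", "HFNC"))
  if (length(bad_tr))
    stopf("encounters.csv row %d: treatment_received must be NIV or HFNC",
          bad_tr[1])
  obs <- data.table::fread(of, na.strings = "")
  miss <- setdiff(.required_obs_cols, names(obs))
  if (length(miss))
    stopf("observations.csv: missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (nrow(obs) && !is.numeric(obs$value))
    stopf("observations.csv: column value must be numeric")
  structure(list(encounters = enc, observations = obs, config = NULL),
            class = "icu_cohort")
}

#' Drop simulator ground-truth columns from an encounter table
#'
#' The leakage guard used by every estimator-facing loader: any column
#' whose name starts with \code{oracle_} is removed.
#'
#' @param encounters encounter data.frame.
#' @return the data.frame without oracle columns.
#' @export
strip_oracle <- function(encounters) {
  encounters[, !startsWith(names(encounters), .oracle_prefix), drop = FALSE]
}
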