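# GPP record I/O and validation. One row per prescription:
# patient_id, age, sex, date, rx_type, rx_code, icd9_code.

#' The six prescription types
#'
#' @return Character vector: Drug, Laboratory Test, Procedures, Rehab,
#'   Referral, Hospital.
#' @export
gpp_rx_types <- function() {
  c("Drug", "Laboratory Test", "Procedures", "Rehab", "Referral", "Hospital")
}

#' Default observation window
#'
#' @param start,end Window bounds (coerced with [as.Date()]); the window is
#'   closed on both ends.
#' @return Date vector of length 2.
#' @export
gpp_window <- function(start = "2002-01-01", end = "2013-12-31") {
  w <- as.Date(c(start, end))
  if (anyNA(w) || w[1] > w[2]) abort("invalid observation window")
  w
}

gpp_columns <- function() {
  c("patient_id", "age", "sex", "date", "rx_type", "rx_code", "icd9_code")
}

#' Validate GPP records
#'
#' Malformed rows are rejected (never repaired) and accounted for in the
#' attached validation report: kept + rejected = input. Rejection reasons, in
#' the order they are checked per row: `missing_value`, `bad_age` (below 15,
#' the general-practice floor - children are seen by pediatricians),
#' `bad_sex`, `bad_rx_type`, `bad_icd9`, `out_of_window`.
#'
#' @param records A data frame with the seven GPP columns.
#' @param window Closed observation window, as from [gpp_window()].
#' @return The kept rows as a tibble, with the report retrievable via
#'   [validation_report()].
#' @export
validate_gpp <- function(records, window = gpp_window()) {
  missing_cols <- setdiff(gpp_columns(), names(records))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(records)[gpp_columns()]
  x$age <- as.integer(x$age)
  x$date <- as.Date(x$date)

  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  has_na <- Reduce(`|`, lapply(x, is.na))
  reason <- flag(has_na, "missing_value")
  reason <- flag(x$age < 15L, "bad_age")
  reason <- flag(!x$sex %in% c("M", "F"), "bad_sex")
  reason <- flag(!x$rx_type %in% gpp_rx_types(), "bad_rx_type")
  reason <- flag(!icd9_valid(x$icd9_code), "bad_icd9")
  reason <- flag(x$date < window[1] | x$date > window[2], "out_of_window")

  kept <- x[is.na(reason), ]
  rej <- reason[!is.na(reason)]
  report <- list(
    n_input = nrow(x),
    n_kept = nrow(kept),
    n_rejected = length(rej),
    reasons = if (length(rej)) {
      count(tibble(reason = rej), .data$reason, name = "n")
    } else {
      tibble(reason = character(), n = integer())
    }
  )
  attr(kept, "validation_report") <- report
  kept
}

#' Retrieve the validation report attached to a validated record set
#'
#' @param records Output of [validate_gpp()] or [read_gpp()].
#' @return A list with `n_input`, `n_kept`, `n_rejected` and a `reasons`
#'   tibble (`reason`, `n`).
#' @export
validation_report <- function(records) {
  rep <- attr(records, "validation_report")
  if (is.null(rep)) abort("records carry no validation report; run validate_gpp()")
  rep
}

#' Read GPP records from CSV
#'
#' Expects the comma-delimited header
#' `patient_id,age,sex,date,rx_type,rx_code,icd9_code` with ISO-8601 dates.
#' Rows failing validation are dropped and counted (see [validate_gpp()]);
#' a missing file or missing column is fatal.
#'
#' @inheritParams validate_gpp
#' @param path CSV file path.
#' @return Validated records tibble with attached validation report.
#' @export
read_gpp <- function(path, window = gpp_window()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      rx_type = readr::col_character(),
      rx_code = readr::col_character(),
      icd9_code = readr::col_character()
    )
  )
  validate_gpp(raw, window = window)
}

#' Write GPP records to CSV
#'
#' Writes the canonical dialect read back by [read_gpp()]; the round trip is
#' the identity on validated records.
#'
#' @param records GPP records tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpp <- function(records, path) {
  readr::write_csv(records[gpp_columns()], path)
  invisible(path)
}
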