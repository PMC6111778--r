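# Cohort stratification: decade age classes from 15, per-patient diabetes
# label from 250.x drug prescriptions, and representativeness checks against
# a reference (census-like) age distribution.

age_class_breaks <- function() c(15L, 25L, 35L, 45L, 55L, 65L, 75L, 85L, 110L)

#' Decade age-class labels
#'
#' Half-open decade classes starting at 15: `(15,25]`, `(25,35]`, ...,
#' `(75,85]`, with `(85,110]` as the terminal class. Age 15 itself belongs to
#' the first class.
#'
#' @return Character vector of the eight class labels, in age order.
#' @export
age_class_labels <- function() {
  b <- age_class_breaks()
  paste0("(", b[-length(b)], ",", b[-1], "]")
}

#' Assign ages to decade classes
#'
#' @param age Integer ages in years, all at least 15 (younger patients are
#'   outside general practice and are rejected at validation).
#' @return Factor over [age_class_labels()], same length as `age`.
#' @export
#' @examples
#' assign_age_class(c(45, 46, 90))
assign_age_class <- function(age) {
  if (anyNA(age) || any(age < 15)) {
    abort("age must be >= 15 (pediatric ages are outside the cohort)")
  }
  if (any(age > 110)) abort("age above the terminal class (85,110]")
  cut(age, breaks = age_class_breaks(), labels = age_class_labels(),
      right = TRUE, include.lowest = TRUE)
}

#' Classify patients as diabetic (D) or non-diabetic (ND)
#'
#' A patient is diabetic iff at least one Drug prescription carries an ICD-9
#' code in 250.00-250.99 (three-digit stem 250). The label is computed from a
#' patient's full record history and is the same in every stratum the patient
#' appears in.
#'
#' @param records Validated GPP records (any number of patients).
#' @return Tibble with one row per patient: `patient_id`, `diabetes`
#'   (`"D"`/`"ND"`).
#' @export
classify_diabetes <- function(records) {
  records |>
    group_by(.data$patient_id) |>
    summarise(
      diabetes = if_else(
        any(.data$rx_type == "Drug" &
              sub("\\..*$", "", .data$icd9_code) == "250"),
        "D", "ND"),
      .groups = "drop")
}

#' Attach the patient-level diabetes label to every record
#'
#' @inheritParams classify_diabetes
#' @return `records` with a `diabetes` column added (existing column replaced).
#' @export
add_diabetes_status <- function(records) {
  records |>
    select(-any_of("diabetes")) |>
    left_join(classify_diabetes(records), by = "patient_id")
}

#' Stratify records by sex, age class, diabetes status and prescription type
#'
#' Records are first labelled patient-globally (diabetes from the full
#' history, age class from `age` at each prescription - a patient ageing
#' across the window contributes to several age strata and is counted once in
#' each stratum's denominator). Scalar filters are applied, then records are
#' split by the `by` dimensions. Empty strata are omitted.
#'
#' @param records Validated GPP records.
#' @param by Character subset of `c("sex", "age_class", "diabetes",
#'   "rx_type")` to split on, or `NULL` for a single pooled stratum.
#' @param sex,diabetes,rx_type Scalar filters (`"all"` keeps everything).
#' @return Tibble with one row per non-empty stratum: the `by` columns, the
#'   scalar filter values for the remaining dimensions, `n_patients`
#'   (distinct patients contributing records), `n_records`, and a `records`
#'   list-column holding the stratum's rows.
#' @export
stratify <- function(records, by = "age_class",
                     sex = "all", diabetes = "all", rx_type = "all") {
  dims <- c("sex", "age_class", "diabetes", "rx_type")
  by <- if (is.null(by)) character(0) else match.arg(by, dims, several.ok = TRUE)
  stopifnot(sex %in% c("all", "M", "F"),
            diabetes %in% c("all", "D", "ND"),
            rx_type %in% c("all", gpp_rx_types()))

  x <- add_diabetes_status(records)
  x$age_class <- assign_age_class(x$age)
  if (sex != "all") x <- filter(x, .data$sex == !!sex)
  if (diabetes != "all") x <- filter(x, .data$diabetes == !!diabetes)
  if (rx_type != "all") x <- filter(x, .data$rx_type == !!rx_type)

  if (length(by)) {
    grouped <- group_by(x, across(all_of(by)))
    out <- group_keys(grouped)
    out$records <- group_split(grouped)  # full rows, grouping columns kept
  } else {
    out <- tibble(records = list(x))
  }
  out <- out |>
    mutate(n_patients = map_int(.data$records,
                                ~n_distinct(.x$patient_id)),
           n_records = map_int(.data$records, nrow)) |>
    relocate("records", .after = last_col())
  # carry the scalar slice values for the dimensions not split on
  fixed <- list(sex = sex, diabetes = diabetes, rx_type = rx_type)
  for (d in setdiff(dims, by)) {
    if (d != "age_class") out[[d]] <- fixed[[d]]
  }
  if ("age_class" %in% by) out <- arrange(out, .data$age_class)
  out
}

#' Compare a sample age distribution with a reference population
#'
#' Per sex: the squared Pearson correlation (r-squared) of the class
#' percentages, and the goodness-of-fit chi-square of the sample counts
#' against the reference proportions. Note the two answer different
#' questions - near-linear class profiles (r-squared near 1) can coexist with
#' a highly significant chi-square difference at large n; both are reported
#' without re-interpretation.
#'
#' @param sample,reference Tibbles with columns `age_class`, `sex`, `count`;
#'   both must cover identical (age_class, sex) bins and reference counts
#'   must be positive.
#' @return Tibble with one row per sex: `sex`, `r_squared`, `chisq`, `df`,
#'   `p_value`.
#' @export
representativeness <- function(sample, reference) {
  need <- c("age_class", "sex", "count")
  stopifnot(all(need %in% names(sample)), all(need %in% names(reference)))
  joined <- inner_join(sample, reference, by = c("age_class", "sex"),
                       suffix = c("_sample", "_ref"))
  if (nrow(joined) != nrow(sample) || nrow(joined) != nrow(reference)) {
    abort("sample and reference age classes do not match")
  }
  if (any(joined$count_ref <= 0)) abort("reference counts must be positive")
  joined |>
    group_by(.data$sex) |>
    summarise(
      r_squared = cor(100 * .data$count_sample / sum(.data$count_sample),
                      100 * .data$count_ref / sum(.data$count_ref))^2,
      chisq = suppressWarnings(
        chisq.test(.data$count_sample,
                   p = .data$count_ref / sum(.data$count_ref))$statistic),
      df = length(.data$count_sample) - 1L,
      p_value = suppressWarnings(
        chisq.test(.data$count_sample,
                   p = .data$count_ref / sum(.data$count_ref))$p.value),
      .groups = "drop")
}
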