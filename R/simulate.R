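# Synthetic GPP generator. Per patient, visit dates are drawn with
# inter-visit gaps uniform in an age-class-dependent range (20-70 days for
# non-diabetics, 17-40 for diabetics, narrowing with age). At each visit a
# set of diagnosis groups is drawn: independent per-group draws plus coupled
# pair draws; each drawn group emits one prescription record whose type
# follows the group's type mix and whose ICD-9 code is a representative code
# of the group. Rates are annual per-patient expectations; the per-visit
# probability is rate / visits-per-year, so expected per-patient counts are
# invariant to visit frequency and configured couplings are recoverable from
# the downstream networks.

#' Reference marginals bundled with the package
#'
#' Marginal counts from a published decade (effective 11 years) of Italian
#' general-practice prescriptions for 14,958 adult patients, used to anchor
#' the generator's defaults: total prescriptions per type, prescriptions per
#' ICD-9 group, and each group's distribution over prescription types (row
#' percents). The EXT group is omitted from the source marginals (count zero,
#' so it never appears in default simulations); its type mix reuses INJ's so
#' that a user-supplied EXT rate still generates plausible records.
#'
#' @return A list: `type_counts` (named, the six types), `group_counts`
#'   (named, 20 groups), `group_type_mix` (20 x 6 matrix of row
#'   probabilities), `n_patients`, `window_years`.
#' @export
gpp_reference <- function() {
  type_counts <- c(
    "Drug" = 897329, "Laboratory Test" = 647023, "Procedures" = 105126,
    "Rehab" = 8388, "Referral" = 65734, "Hospital" = 5136)
  group_counts <- c(
    CIRC = 451765, META = 231541, ILL = 219664, DIGE = 133736, MUSC = 122718,
    GEN = 112029, RESP = 110587, SUPP = 75458, NEOP = 72708, MENT = 45328,
    NERV = 28969, BLD = 28406, SENS = 26879, SKIN = 22250, INFE = 21803,
    INJ = 20342, PREG = 2748, CONG = 1401, NEWB = 404, EXT = 0)
  pct <- rbind(
    CIRC = c(69.2, 25.4, 3.5, 0.0, 1.8, 0.2),
    META = c(37.6, 56.6, 2.5, 0.0, 3.3, 0.1),
    ILL  = c(26.7, 56.4, 10.7, 1.0, 4.8, 0.5),
    DIGE = c(72.6, 20.4, 4.8, 0.0, 1.9, 0.3),
    MUSC = c(57.4, 22.2, 11.8, 3.7, 4.6, 0.3),
    GEN  = c(37.6, 51.6, 6.7, 0.0, 3.8, 0.3),
    RESP = c(87.1, 6.9, 3.2, 0.1, 2.5, 0.2),
    SUPP = c(13.0, 76.9, 6.5, 0.1, 3.3, 0.3),
    NEOP = c(15.2, 67.7, 12.2, 0.0, 4.0, 0.9),
    MENT = c(89.5, 4.9, 0.7, 0.0, 4.8, 0.1),
    NERV = c(69.0, 16.9, 7.3, 0.4, 5.8, 0.6),
    BLD  = c(20.5, 75.6, 1.3, 0.0, 2.4, 0.2),
    SENS = c(57.1, 5.3, 14.0, 0.0, 22.0, 1.5),
    SKIN = c(44.3, 36.2, 3.7, 0.1, 15.4, 0.4),
    INFE = c(49.5, 33.1, 11.5, 0.1, 5.6, 0.2),
    INJ  = c(40.1, 14.7, 21.7, 5.3, 17.5, 0.7),
    PREG = c(41.9, 48.2, 4.4, 0.0, 3.2, 2.2),
    CONG = c(24.1, 42.1, 18.6, 1.1, 10.5, 3.5),
    NEWB = c(66.6, 21.0, 2.0, 0.0, 8.9, 1.5))
  pct <- rbind(pct, EXT = pct["INJ", ])
  colnames(pct) <- gpp_rx_types()
  pct <- pct[icd9_group_labels(), ]
  mix <- sweep(pct, 1, rowSums(pct), "/")
  list(type_counts = type_counts,
       group_counts = group_counts[icd9_group_labels()],
       group_type_mix = mix,
       n_patients = 14958L, window_years = 11)
}

#' Population configuration for the synthetic generator
#'
#' Defaults match the reference cohort: 14,958 patients, 48.4% male
#' (7246/14958), 7.7% diabetes prevalence, and a census-like adult age
#' structure over the eight decade classes.
#'
#' @param n_patients Number of patients.
#' @param male_fraction Fraction of males.
#' @param age_weights Named non-negative weights over [age_class_labels()];
#'   normalized to sum to 1.
#' @param diabetes_prevalence Fraction of diabetic patients.
#' @return A `population_config` list.
#' @export
population_config <- function(n_patients = 14958,
                              male_fraction = 7246 / 14958,
                              age_weights = c(
                                "(15,25]" = 0.12, "(25,35]" = 0.15,
                                "(35,45]" = 0.16, "(45,55]" = 0.16,
                                "(55,65]" = 0.15, "(65,75]" = 0.13,
                                "(75,85]" = 0.09, "(85,110]" = 0.04),
                              diabetes_prevalence = 0.077) {
  stopifnot(n_patients >= 0, male_fraction >= 0, male_fraction <= 1,
            diabetes_prevalence >= 0, diabetes_prevalence <= 1)
  if (!setequal(names(age_weights), age_class_labels()) ||
      any(age_weights < 0) || sum(age_weights) <= 0) {
    abort("age_weights must be non-negative weights named by the age classes")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         male_fraction = male_fraction,
         age_weights = age_weights[age_class_labels()] / sum(age_weights),
         diabetes_prevalence = diabetes_prevalence),
    class = "population_config")
}

default_visit_gaps <- function() {
  tibble(
    age_class = age_class_labels(),
    nd_lo = c(48, 44, 40, 36, 32, 27, 23, 20),
    nd_hi = c(70, 66, 62, 56, 50, 44, 38, 32),
    d_lo = c(28, 26, 24, 22, 20, 19, 18, 17),
    d_hi = c(40, 38, 36, 33, 30, 28, 26, 24))
}

default_coupling <- function() {
  tibble(
    group_a = c("CIRC", "CIRC", "CIRC", "CIRC", "CIRC", "DIGE", "GEN", "META"),
    group_b = c("DIGE", "GEN", "META", "MUSC", "RESP", "META", "META", "RESP"),
    rate = c(0.25, 0.15, 0.60, 0.20, 0.20, 0.12, 0.12, 0.10),
    diabetes_mult = c(1.5, 1.5, 12, 1.5, 1.5, 12, 12, 12))
}

#' Morbidity model for the synthetic generator
#'
#' All rates are expected annual prescription counts per patient. Defaults
#' derive from the bundled reference marginals ([gpp_reference()]): per-group
#' base rates are the reference group counts divided by patients and window
#' years, and each group's prescription-type mix is the reference row mix.
#' The age profile multiplies all rates (morbidity and coupling), rising with
#' age and dipping in the terminal class (survivor effect). Diabetic patients
#' get multiplied per-group rates (META and CIRC most strongly), multiplied
#' pair couplings (12x on pairs involving META by default, within the 10-20x
#' comorbidity enrichment such cohorts display), shorter visit intervals
#' (17-40 days vs 20-70), and a per-visit probability `refill_prob` of a
#' diabetes drug prescription (ICD-9 250.x under Drug), which is what the
#' diabetes classifier keys on.
#'
#' @param base_rates Named annual per-group rates (all 20 groups).
#' @param age_profile Named multiplier per age class.
#' @param coupling Tibble `group_a < group_b`, `rate` (annual pair
#'   co-prescription rate per patient), `diabetes_mult`.
#' @param diabetes_rate_mult Named per-group rate multipliers for diabetics.
#' @param visit_gaps Tibble `age_class`, `nd_lo`, `nd_hi`, `d_lo`, `d_hi`
#'   (days); non-diabetic ranges must lie within \[20, 70\], diabetic within
#'   \[17, 40\].
#' @param type_mix 20 x 6 matrix of row probabilities (groups x types).
#' @param refill_prob Per-visit diabetes-drug probability for diabetics.
#' @return A `morbidity_model` list.
#' @export
morbidity_model <- function(base_rates = NULL,
                            age_profile = c(
                              "(15,25]" = 0.45, "(25,35]" = 0.60,
                              "(35,45]" = 0.80, "(45,55]" = 1.00,
                              "(55,65]" = 1.30, "(65,75]" = 1.60,
                              "(75,85]" = 1.80, "(85,110]" = 1.20),
                            coupling = default_coupling(),
                            diabetes_rate_mult = NULL,
                            visit_gaps = default_visit_gaps(),
                            type_mix = NULL,
                            refill_prob = 0.5) {
  ref <- gpp_reference()
  groups <- icd9_group_labels()
  if (is.null(base_rates)) {
    base_rates <- ref$group_counts / (ref$n_patients * ref$window_years)
  }
  if (is.null(type_mix)) type_mix <- ref$group_type_mix
  if (is.null(diabetes_rate_mult)) {
    diabetes_rate_mult <- stats::setNames(rep(1.3, length(groups)), groups)
    diabetes_rate_mult["META"] <- 3
    diabetes_rate_mult["CIRC"] <- 2
  }
  stopifnot(
    setequal(names(base_rates), groups), all(base_rates >= 0),
    setequal(names(age_profile), age_class_labels()), all(age_profile > 0),
    setequal(names(diabetes_rate_mult), groups), all(diabetes_rate_mult >= 0),
    all(c("group_a", "group_b", "rate", "diabetes_mult") %in% names(coupling)),
    all(coupling$group_a < coupling$group_b),
    all(coupling$rate >= 0), all(coupling$diabetes_mult >= 0),
    all(coupling$group_a %in% groups), all(coupling$group_b %in% groups),
    identical(visit_gaps$age_class, age_class_labels()),
    all(visit_gaps$nd_lo >= 20), all(visit_gaps$nd_hi <= 70),
    all(visit_gaps$d_lo >= 17), all(visit_gaps$d_hi <= 40),
    all(visit_gaps$nd_lo <= visit_gaps$nd_hi),
    all(visit_gaps$d_lo <= visit_gaps$d_hi),
    nrow(type_mix) == length(groups),
    max(abs(rowSums(type_mix) - 1)) < 1e-8,
    refill_prob >= 0, refill_prob <= 1)
  rownames(type_mix) <- rownames(type_mix) %||% groups
  structure(
    list(base_rates = base_rates[groups],
         age_profile = age_profile[age_class_labels()],
         coupling = as_tibble(coupling),
         diabetes_rate_mult = diabetes_rate_mult[groups],
         visit_gaps = visit_gaps,
         type_mix = type_mix[groups, gpp_rx_types()],
         refill_prob = refill_prob),
    class = "morbidity_model")
}

#' Simulate a patient population
#'
#' Reproducible given `seed`; with `seed = NULL` the current RNG state is
#' used (so a caller can seed once for a whole dataset).
#'
#' @param config A [population_config()].
#' @param window_start Date at which sampled ages hold; birth years are
#'   derived from it and ages advance across the observation window.
#' @param seed Optional integer seed.
#' @return Tibble: `patient_id`, `sex`, `birth_year`, `diabetic`.
#' @export
simulate_population <- function(config = population_config(),
                                window_start = gpp_window()[1],
                                seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  if (n == 0L) {
    return(tibble(patient_id = character(), sex = character(),
                  birth_year = integer(), diabetic = logical()))
  }
  breaks <- age_class_breaks()
  cls <- sample.int(length(config$age_weights), n, replace = TRUE,
                    prob = config$age_weights)
  lo <- breaks[cls]
  hi <- pmin(breaks[cls + 1L], 99L)  # cap sampled ages at 99 in the top class
  # half-open (lo, hi]; age 15 admitted in the first class
  age <- lo + sample_int_vec(hi - lo, floor = ifelse(lo == 15L, 0L, 1L))
  tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = ifelse(runif(n) < config$male_fraction, "M", "F"),
    birth_year = lubridate::year(as.Date(window_start)) - age,
    diabetic = runif(n) < config$diabetes_prevalence)
}

# vectorized sample of integers in [floor, width] per element
sample_int_vec <- function(width, floor) {
  floor + floor(runif(length(width)) * (width - floor + 1))
}

age_class_index <- function(age) {
  cut(pmin(age, 110L), breaks = age_class_breaks(), labels = FALSE,
      right = TRUE, include.lowest = TRUE)
}

#' Simulate prescription records for a patient population
#'
#' See the package's model description: uniform inter-visit gaps in the
#' age/diabetes-appropriate range, per-visit independent group draws plus
#' coupled pair draws at probability rate/visits-per-year, diabetic refill
#' prescriptions (Drug, ICD-9 250.x), ages derived per record from birth
#' year and visit date.
#'
#' @param patients Output of [simulate_population()].
#' @param model A [morbidity_model()].
#' @param window Closed observation window ([gpp_window()]).
#' @param seed Optional integer seed.
#' @return Validated-schema GPP records tibble.
#' @export
simulate_gpp <- function(patients, model = morbidity_model(),
                         window = gpp_window(), seed = NULL) {
  stopifnot(inherits(model, "morbidity_model"))
  if (!is.null(seed)) set.seed(seed)
  empty <- tibble(patient_id = character(), age = integer(),
                  sex = character(), date = as.Date(character()),
                  rx_type = character(), rx_code = character(),
                  icd9_code = character())
  n <- nrow(patients)
  if (n == 0L) return(empty)
  start <- window[1]
  horizon <- as.numeric(window[2] - window[1])
  # calendar year from day offset without per-call date arithmetic
  yrs <- seq(lubridate::year(start), lubridate::year(window[2]) + 1L)
  year_start_off <- as.numeric(as.Date(paste0(yrs, "-01-01")) - start)
  day_year <- function(day) yrs[findInterval(day, year_start_off)]

  gaps <- model$visit_gaps
  glo <- cbind(nd = gaps$nd_lo, d = gaps$d_lo)
  ghi <- cbind(nd = gaps$nd_hi, d = gaps$d_hi)
  status <- ifelse(patients$diabetic, 2L, 1L)

  draw_gap <- function(idx_patient, day) {
    age <- day_year(floor(day)) - patients$birth_year[idx_patient]
    ci <- age_class_index(age)
    m <- cbind(ci, status[idx_patient])
    runif(length(idx_patient), glo[m], ghi[m])
  }

  # visit schedule: iterate over visit index, vectorized across patients
  active <- seq_len(n)
  cur <- runif(n) * draw_gap(active, rep(0, n))  # stationary-start offset
  vis_p <- list(); vis_day <- list(); k <- 0L
  while (length(active)) {
    inw <- cur[active] <= horizon
    active <- active[inw]
    if (!length(active)) break
    k <- k + 1L
    vis_p[[k]] <- active
    vis_day[[k]] <- floor(cur[active])
    cur[active] <- cur[active] + draw_gap(active, cur[active])
  }
  if (k == 0L) return(empty)
  vp <- unlist(vis_p)          # patient row index per visit
  vday <- unlist(vis_day)
  vdate <- start + vday
  vage <- day_year(vday) - patients$birth_year[vp]
  vci <- age_class_index(vage)
  vdiab <- patients$diabetic[vp]
  mean_gap <- (glo[cbind(vci, status[vp])] + ghi[cbind(vci, status[vp])]) / 2
  vpy <- 365.25 / mean_gap     # visits per year, by current class/status
  amult <- unname(model$age_profile[vci])
  nv <- length(vp)

  rec_visit <- integer(0); rec_group <- character(0)
  # independent per-group draws
  for (g in names(model$base_rates)[model$base_rates > 0]) {
    p <- model$base_rates[[g]] * amult *
      ifelse(vdiab, model$diabetes_rate_mult[[g]], 1) / vpy
    hit <- which(runif(nv) < pmin(p, 0.95))
    rec_visit <- c(rec_visit, hit)
    rec_group <- c(rec_group, rep(g, length(hit)))
  }
  # coupled pair draws: one record of each group of the pair
  cp <- model$coupling[model$coupling$rate > 0, ]
  for (i in seq_len(nrow(cp))) {
    p <- cp$rate[i] * amult * ifelse(vdiab, cp$diabetes_mult[i], 1) / vpy
    hit <- which(runif(nv) < pmin(p, 0.95))
    rec_visit <- c(rec_visit, hit, hit)
    rec_group <- c(rec_group,
                   rep(cp$group_a[i], length(hit)),
                   rep(cp$group_b[i], length(hit)))
  }
  # sample codes and types per group
  codes <- group_example_codes()
  rec_code <- character(length(rec_group))
  rec_type <- character(length(rec_group))
  for (g in unique(rec_group)) {
    sel <- rec_group == g
    m <- sum(sel)
    rec_code[sel] <- sample(codes[[g]], m, replace = TRUE)
    rec_type[sel] <- sample(gpp_rx_types(), m, replace = TRUE,
                            prob = model$type_mix[g, ])
  }
  # diabetic refill prescriptions: Drug with a 250.x code
  dref <- which(vdiab & runif(nv) < model$refill_prob)
  rec_visit <- c(rec_visit, dref)
  rec_group <- c(rec_group, rep("META", length(dref)))
  rec_code <- c(rec_code, sample(diabetes_codes(), length(dref), replace = TRUE))
  rec_type <- c(rec_type, rep("Drug", length(dref)))

  if (!length(rec_visit)) return(empty)
  tibble(
    patient_id = patients$patient_id[vp[rec_visit]],
    age = as.integer(vage[rec_visit]),
    sex = patients$sex[vp[rec_visit]],
    date = vdate[rec_visit],
    rx_type = rec_type,
    rx_code = sprintf("RX%05d", sample.int(99999L, length(rec_visit),
                                           replace = TRUE)),
    icd9_code = rec_code) |>
    arrange(.data$patient_id, .data$date)
}

#' Simulate a complete synthetic GPP dataset
#'
#' One seed governs population and prescriptions; identical seeds give
#' identical datasets.
#'
#' @param config A [population_config()].
#' @param model A [morbidity_model()].
#' @param window Closed observation window.
#' @param seed Integer seed.
#' @return List with `patients` and `records` tibbles.
#' @export
simulate_dataset <- function(config = population_config(),
                             model = morbidity_model(),
                             window = gpp_window(), seed = 1L) {
  set.seed(seed)
  patients <- simulate_population(config, window_start = window[1])
  records <- simulate_gpp(patients, model, window = window)
  list(patients = patients, records = records)
}
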