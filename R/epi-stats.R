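# Tabular and curve statistics: prescription-type frequency summaries,
# morbidity (prescriptions per patient) and comorbidity (network strength per
# patient) age curves, META-anchored D/ND co-prescription profiles, exact
# Poisson (Garwood) confidence intervals and the diabetic/non-diabetic rate
# ratio with a conditional-binomial exact CI.

count_by <- function(x, what) {
  if (is.data.frame(x)) {
    v <- if (what == "group" && !"group" %in% names(x)) {
      map_code_to_group(x$icd9_code)
    } else {
      x[[what]]
    }
    cnt <- table(factor(v, levels = if (what == "rx_type")
      gpp_rx_types() else icd9_group_labels()))
    cnt <- stats::setNames(as.numeric(cnt), names(cnt))
    cnt[cnt > 0]
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    x
  }
}

#' Summarize prescriptions by type
#'
#' Percent of total and (when denominators are supplied) prescriptions per
#' patient per year, overall and per type. Values are kept at full precision;
#' round only at presentation.
#'
#' @param x Validated GPP records, or a named numeric vector of per-type
#'   counts (names among [gpp_rx_types()]).
#' @param n_patients,window_years Optional denominators for the per-patient
#'   per-year column. `window_years` is always an explicit input: published
#'   per-patient rates can imply an effective window differing from the
#'   calendar span, so it is never inferred from dates.
#' @return Tibble with an `All` row followed by one row per type:
#'   `rx_type`, `n`, `pct_of_total`, `per_patient_year`.
#' @export
summarize_by_type <- function(x, n_patients = NULL, window_years = NULL) {
  cnt <- count_by(x, "rx_type")
  stopifnot(all(names(cnt) %in% gpp_rx_types()))
  cnt <- cnt[intersect(gpp_rx_types(), names(cnt))]
  total <- sum(cnt)
  if (!is.null(n_patients)) {
    stopifnot(window_years > 0)
    if (n_patients == 0 && total > 0) abort("records but zero patients")
  }
  ppy <- function(n) {
    if (is.null(n_patients) || is.null(window_years)) return(NA_real_)
    n / (n_patients * window_years)
  }
  tibble(
    rx_type = c("All", names(cnt)),
    n = c(total, unname(cnt)),
    pct_of_total = 100 * .data$n / total,
    per_patient_year = map_dbl(.data$n, ppy))
}

#' Summarize prescription-type mix per ICD-9 group
#'
#' One row per group present in the records: total count and the row-wise
#' percent of each prescription type, sorted by count descending.
#'
#' @param records Validated GPP records.
#' @param group_map Mapping table, as from [default_group_map()].
#' @return Tibble: `group`, `n`, then one percent column per type.
#' @export
summarize_group_by_type <- function(records, group_map = default_group_map()) {
  if (nrow(records) == 0) {
    out <- tibble(group = character(), n = numeric())
    for (t in gpp_rx_types()) out[[t]] <- numeric()
    return(out)
  }
  records |>
    mutate(group = map_code_to_group(.data$icd9_code, group_map),
           rx_type = factor(.data$rx_type, levels = gpp_rx_types())) |>
    count(.data$group, .data$rx_type, .drop = FALSE) |>
    group_by(.data$group) |>
    mutate(total = sum(.data$n), pct = 100 * .data$n / .data$total) |>
    ungroup() |>
    filter(.data$total > 0) |>
    select("group", n = "total", "rx_type", "pct") |>
    tidyr::pivot_wider(names_from = "rx_type", values_from = "pct") |>
    arrange(desc(.data$n))
}

#' Share of total prescriptions held by a set of groups
#'
#' @param x Validated GPP records, or a named numeric vector of per-group
#'   counts.
#' @param groups Character vector of group labels (subset of the 20).
#' @return Fraction in \[0, 1\].
#' @export
selected_groups_share <- function(x, groups) {
  bad <- setdiff(groups, icd9_group_labels())
  if (length(bad)) abort(paste0("unknown group label(s): ",
                                paste(bad, collapse = ", ")))
  cnt <- count_by(x, "group")
  stopifnot(all(names(cnt) %in% icd9_group_labels()))
  sum(cnt[names(cnt) %in% groups]) / sum(cnt)
}

#' Morbidity age curve: mean prescriptions per patient per stratum
#'
#' @param strata Output of [stratify()] (typically split by `age_class`,
#'   possibly also by `diabetes`). Empty strata never appear (they are
#'   omitted by [stratify()], not reported as zero).
#' @return `strata` without the `records` column, with a `value` column =
#'   n_records / n_patients.
#' @export
morbidity_curve <- function(strata) {
  strata |>
    mutate(value = .data$n_records / .data$n_patients) |>
    select(-"records")
}

#' Comorbidity age curve: total network strength per patient per stratum
#'
#' For each stratum the per-patient-normalized comorbidity network is built
#' and the strengths of all nodes are summed; by the handshake identity this
#' equals twice the sum of normalized link weights - one scalar comorbidity
#' measure per stratum.
#'
#' @inheritParams morbidity_curve
#' @param cooccur Co-occurrence unit passed to [co_events()].
#' @return `strata` without `records`, with a `value` column.
#' @export
comorbidity_curve <- function(strata, cooccur = "visit") {
  strata |>
    mutate(value = map2_dbl(.data$records, .data$n_patients, function(r, np) {
      net <- normalize_network(build_network(co_events(r, cooccur), np))
      2 * sum(net$edges$weight)
    })) |>
    select(-"records")
}

#' META-anchored co-prescription profile for diabetic vs non-diabetic strata
#'
#' For each group, the raw number of co-prescription events with the anchor
#' group (META by default) in the diabetic and non-diabetic stratum, and the
#' corresponding per-patient rates.
#'
#' @param stratum_d,stratum_nd One-row stratum tibbles from [stratify()]
#'   (or lists with `records` and `n_patients`), sharing the same sex/age
#'   slice.
#' @param groups Optional group labels to restrict the profile to.
#' @param anchor Anchor group label.
#' @param cooccur Co-occurrence unit passed to [co_events()].
#' @return Tibble: `group`, `count_d`, `count_nd`, `n_d`, `n_nd`, `rate_d`,
#'   `rate_nd`. Groups with no co-events in either stratum get zero counts.
#' @export
meta_coprescription_profile <- function(stratum_d, stratum_nd, groups = NULL,
                                        anchor = "META", cooccur = "visit") {
  pull_stratum <- function(s) {
    if (is.data.frame(s)) s <- as.list(s[1, ])
    list(records = if (is.list(s$records) && is.data.frame(s$records[[1]]))
      s$records[[1]] else s$records,
      n_patients = s$n_patients[[1]])
  }
  d <- pull_stratum(stratum_d)
  nd <- pull_stratum(stratum_nd)
  anchor_edges <- function(s) {
    net <- build_network(co_events(s$records, cooccur), s$n_patients)
    net$edges |>
      filter(.data$group_a == anchor | .data$group_b == anchor) |>
      transmute(group = if_else(.data$group_a == anchor,
                                .data$group_b, .data$group_a),
                count = .data$weight)
  }
  out <- full_join(anchor_edges(d), anchor_edges(nd), by = "group",
                   suffix = c("_d", "_nd")) |>
    mutate(across(c("count_d", "count_nd"), ~tidyr::replace_na(.x, 0)))
  if (!is.null(groups)) {
    out <- out |>
      full_join(tibble(group = groups), by = "group") |>
      filter(.data$group %in% groups) |>
      mutate(across(c("count_d", "count_nd"), ~tidyr::replace_na(.x, 0)))
  }
  out |>
    mutate(n_d = d$n_patients, n_nd = nd$n_patients,
           rate_d = .data$count_d / .data$n_d,
           rate_nd = .data$count_nd / .data$n_nd) |>
    arrange(desc(.data$rate_d))
}

#' Exact (Garwood) confidence interval for a Poisson mean
#'
#' Gamma-quantile interval: for count k at level 1-a, the lower bound is the
#' a/2 quantile of Gamma(k) (0 when k = 0) and the upper bound the 1-a/2
#' quantile of Gamma(k+1). A normal approximation (k +/- z sqrt(k)) is
#' available for comparison.
#'
#' @param k Non-negative integer counts (vectorized).
#' @param level Confidence level in (0, 1).
#' @param method `"garwood"` (exact, default) or `"normal"`.
#' @return Tibble: `k`, `lo`, `hi`.
#' @export
#' @examples
#' poisson_ci(c(0, 100))
poisson_ci <- function(k, level = 0.95, method = c("garwood", "normal")) {
  method <- match.arg(method)
  if (any(k < 0) || any(k != floor(k))) abort("k must be non-negative integers")
  stopifnot(level > 0, level < 1)
  a <- 1 - level
  if (method == "garwood") {
    lo <- ifelse(k == 0, 0, qgamma(a / 2, shape = k))
    hi <- qgamma(1 - a / 2, shape = k + 1)
  } else {
    z <- qnorm(1 - a / 2)
    lo <- pmax(0, k - z * sqrt(k))
    hi <- k + z * sqrt(k)
  }
  tibble(k = k, lo = lo, hi = hi)
}

#' Diabetic vs non-diabetic co-prescription rate ratio
#'
#' Point estimate (count_d/n_d)/(count_nd/n_nd) with an exact CI from the
#' conditional-binomial construction: conditional on the total count,
#' count_d is binomial with success probability p, the Clopper-Pearson
#' interval for p is transformed to the rate-ratio scale by
#' p/(1-p) * n_nd/n_d. When count_nd = 0 the ratio is infinite and only the
#' lower bound is finite (one-sided).
#'
#' @param count_d,count_nd Co-prescription event counts (vectorized).
#' @param n_d,n_nd Patient denominators (>= 1).
#' @param level Confidence level.
#' @return Tibble: the inputs plus `rate_d`, `rate_nd`, `ratio`, `ci_lo`,
#'   `ci_hi`, `level`.
#' @export
#' @examples
#' dn_ratio(100, 10, 10, 10)
dn_ratio <- function(count_d, n_d, count_nd, n_nd, level = 0.95) {
  stopifnot(all(count_d >= 0), all(count_nd >= 0),
            all(n_d >= 1), all(n_nd >= 1), level > 0, level < 1)
  one <- function(kd, nd, knd, nnd) {
    scale <- nnd / nd
    if (kd + knd == 0) {
      return(tibble(ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
    }
    ci_p <- binom.test(round(kd), round(kd + knd),
                       conf.level = level)$conf.int
    odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
    tibble(
      ratio = if (knd == 0) Inf else (kd / nd) / (knd / nnd),
      ci_lo = odds(ci_p[1]) * scale,
      ci_hi = odds(ci_p[2]) * scale)
  }
  args <- tibble(count_d = count_d, n_d = n_d,
                 count_nd = count_nd, n_nd = n_nd)
  est <- pmap(list(args$count_d, args$n_d, args$count_nd, args$n_nd), one) |>
    purrr::list_rbind()
  args |>
    mutate(rate_d = count_d / n_d, rate_nd = count_nd / n_nd) |>
    bind_cols(est) |>
    mutate(level = level)
}

#' D/ND rate ratios for a META co-prescription profile
#'
#' @param profile Output of [meta_coprescription_profile()].
#' @param level Confidence level.
#' @return `profile` joined with `ratio`, `ci_lo`, `ci_hi`, `level`.
#' @export
dn_ratio_profile <- function(profile, level = 0.95) {
  est <- dn_ratio(profile$count_d, profile$n_d,
                  profile$count_nd, profile$n_nd, level = level)
  bind_cols(profile, select(est, "ratio", "ci_lo", "ci_hi", "level"))
}

#' Plot morbidity/comorbidity age curves
#'
#' @param curve Output of [morbidity_curve()] or [comorbidity_curve()],
#'   possibly row-bound across populations with a distinguishing column
#'   (e.g. `diabetes`).
#' @param color Name of the column distinguishing the series (default
#'   `"diabetes"` when present).
#' @return A ggplot object.
#' @export
plot_age_curve <- function(curve, color = NULL) {
  color <- color %||% (if ("diabetes" %in% names(curve)) "diabetes")
  aes <- if (is.null(color)) {
    ggplot2::aes(x = .data$age_class, y = .data$value, group = 1)
  } else {
    ggplot2::aes(x = .data$age_class, y = .data$value,
                 color = .data[[color]], group = .data[[color]])
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age class", y = "per patient") +
    ggplot2::theme_minimal()
}

#' Plot D/ND rate ratios with confidence intervals
#'
#' @param ratios Output of [dn_ratio_profile()].
#' @return A ggplot object.
#' @export
plot_dn_ratio <- function(ratios) {
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::labs(x = NULL, y = "D/ND co-prescription rate ratio") +
    ggplot2::theme_minimal()
}
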