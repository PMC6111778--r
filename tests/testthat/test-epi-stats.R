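test_that("type summaries conserve counts and percentages", {
  rec <- dplyr::bind_rows(
    make_records(rx_code = as.character(1:7)),
    make_records(rx_type = "Laboratory Test", rx_code = as.character(8:10)))
  s <- summarize_by_type(rec, n_patients = 1, window_years = 10)
  expect_equal(s$n[s$rx_type == "All"], 10)
  expect_equal(sum(s$n[s$rx_type != "All"]), 10)
  expect_equal(sum(s$pct_of_total[s$rx_type != "All"]), 100)
  expect_equal(s$per_patient_year[s$rx_type == "All"], 1)
  # a single type takes 100%
  one <- summarize_by_type(make_records())
  expect_equal(one$pct_of_total[one$rx_type == "Drug"], 100)
  expect_error(summarize_by_type(rec, n_patients = 0, window_years = 10),
               "zero patients")
})

test_that("group-by-type rows hold row percentages and conserve totals", {
  rec <- dplyr::bind_rows(
    make_records(rx_code = as.character(1:7)),                          # CIRC Drug
    make_records(rx_type = "Laboratory Test", rx_code = as.character(8:10)),
    make_records(icd9_code = "250.00", rx_code = "m1"))                 # META
  g <- summarize_group_by_type(rec)
  circ <- g[g$group == "CIRC", ]
  expect_equal(circ$n, 10)
  expect_equal(circ$Drug, 70)
  expect_equal(circ$`Laboratory Test`, 30)
  expect_equal(circ$Procedures, 0)
  expect_equal(sum(g$n), nrow(rec))
  # every row's percentages sum to 100
  pct <- as.matrix(g[, gpp_rx_types()])
  expect_equal(unname(rowSums(pct)), rep(100, nrow(g)))
  expect_equal(nrow(summarize_group_by_type(make_records()[0, ])), 0L)
})

test_that("selected group shares are plain count fractions", {
  cnt <- c(CIRC = 60, META = 30, RESP = 10)
  expect_equal(selected_groups_share(cnt, c("CIRC", "META")), 0.9)
  expect_equal(selected_groups_share(cnt, icd9_group_labels()), 1)
  expect_equal(selected_groups_share(cnt, character(0)), 0)
  expect_error(selected_groups_share(cnt, "BOGUS"), "unknown group")
  # records route agrees with the count route
  rec <- dplyr::bind_rows(make_records(rx_code = as.character(1:3)),
                          make_records(icd9_code = "250.00", rx_code = "x"))
  expect_equal(selected_groups_share(rec, "CIRC"), 0.75)
})

test_that("morbidity and comorbidity curves compute per-patient values", {
  rec <- make_records(patient_id = rep(sprintf("P%02d", 1:10), each = 15),
                      rx_code = as.character(1:150))
  s <- stratify(rec, by = "age_class")
  expect_equal(morbidity_curve(s)$value, 15)

  # single CIRC-META link of raw weight 3 across 3 patients: 2 * 3 / 3 = 2
  rec2 <- dplyr::bind_rows(
    make_records(patient_id = rep(c("A", "B", "C"), each = 1),
                 rx_code = as.character(1:3)),
    make_records(patient_id = c("A", "B", "C"), icd9_code = "272.0",
                 rx_code = as.character(4:6)))
  s2 <- stratify(rec2, by = "age_class")
  expect_equal(comorbidity_curve(s2)$value, 2)
  # identity with the network module's strengths
  net <- normalize_network(build_network(co_events(rec2), 3))
  expect_equal(comorbidity_curve(s2)$value, sum(node_strength(net)$strength))
})

test_that("META co-prescription profiles count anchor links per patient", {
  mk <- function(patients, n_events, other = "401.9") {
    purrr::map(seq_len(n_events), function(i) dplyr::bind_rows(
      make_records(patient_id = patients[1 + (i %% length(patients))],
                   date = as.Date("2005-01-01") + 30 * i,
                   rx_code = paste0("a", i), icd9_code = other),
      make_records(patient_id = patients[1 + (i %% length(patients))],
                   date = as.Date("2005-01-01") + 30 * i,
                   rx_code = paste0("b", i), icd9_code = "272.0"))) |>
      purrr::list_rbind()
  }
  stratum_d <- list(records = mk(c("D1", "D2"), 10), n_patients = 2)
  stratum_nd <- list(records = mk(c("N1", "N2"), 4), n_patients = 2)
  prof <- meta_coprescription_profile(stratum_d, stratum_nd)
  expect_equal(prof$count_d[prof$group == "CIRC"], 10)
  expect_equal(prof$rate_d[prof$group == "CIRC"], 5)
  expect_equal(prof$rate_nd[prof$group == "CIRC"], 2)
  # absent groups report zero, not an error
  prof2 <- meta_coprescription_profile(stratum_d, stratum_nd,
                                       groups = c("CIRC", "RESP"))
  expect_equal(prof2$count_d[prof2$group == "RESP"], 0)
  expect_equal(prof2$rate_nd[prof2$group == "RESP"], 0)
})

test_that("Garwood intervals match the chi-square formulation and nest", {
  # independent route: qchisq(a/2, 2k)/2 and qchisq(1-a/2, 2k+2)/2
  k <- 0:50
  ci <- poisson_ci(k)
  expect_equal(ci$lo,
               ifelse(k == 0, 0, stats::qchisq(0.025, 2 * k) / 2))
  expect_equal(ci$hi, stats::qchisq(0.975, 2 * k + 2) / 2)
  expect_equal(poisson_ci(0)$hi, 3.688879, tolerance = 1e-6)
  expect_equal(poisson_ci(100)$lo, 81.36399, tolerance = 1e-6)
  expect_equal(poisson_ci(100)$hi, 121.6268, tolerance = 1e-6)
  # nesting: 99% interval contains the 95% interval for every k
  k2 <- 0:1000
  ci95 <- poisson_ci(k2, 0.95)
  ci99 <- poisson_ci(k2, 0.99)
  expect_true(all(ci99$lo <= ci95$lo & ci99$hi >= ci95$hi))
  expect_error(poisson_ci(-1), "non-negative")
  # normal approximation stays close at large k
  n100 <- poisson_ci(100, method = "normal")
  expect_equal(n100$lo, 100 - 1.959964 * 10, tolerance = 1e-5)
})

test_that("D/ND rate ratios and their conditional CIs behave", {
  r <- dn_ratio(100, 10, 10, 10)
  expect_equal(r$ratio, 10)
  expect_true(r$ci_lo < 10 && r$ci_hi > 10)

  eq <- dn_ratio(50, 10, 50, 10)
  expect_equal(eq$ratio, 1)
  expect_true(eq$ci_lo < 1 && eq$ci_hi > 1)

  # equivariance: scaling counts and denominators preserves the ratio and
  # narrows the interval
  small <- dn_ratio(20, 10, 10, 10)
  big <- dn_ratio(80, 40, 40, 40)
  expect_equal(small$ratio, big$ratio)
  expect_lt(big$ci_hi - big$ci_lo, small$ci_hi - small$ci_lo)

  # unequal denominators rescale the ratio
  expect_equal(dn_ratio(100, 10, 10, 100)$ratio, 100)

  # zero reference count: infinite ratio with a finite lower bound
  z <- dn_ratio(10, 5, 0, 5)
  expect_equal(z$ratio, Inf)
  expect_true(is.finite(z$ci_lo) && z$ci_lo > 0)
  expect_equal(z$ci_hi, Inf)
})

test_that("ratio profiles join estimates onto the co-prescription table", {
  prof <- tibble::tibble(group = c("CIRC", "RESP"),
                         count_d = c(100, 40), count_nd = c(10, 8),
                         n_d = 10, n_nd = 10,
                         rate_d = c(10, 4), rate_nd = c(1, 0.8))
  out <- dn_ratio_profile(prof)
  expect_equal(out$ratio, c(10, 5))
  expect_true(all(out$ci_lo < out$ratio & out$ratio < out$ci_hi))
  p <- plot_dn_ratio(out)
  expect_s3_class(p, "ggplot")
})
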