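# In-code fixtures: small record sets and model configurations reused across
# test files.

make_records <- function(patient_id = "P1", age = 50L, sex = "M",
                         date = as.Date("2005-06-01"), rx_type = "Drug",
                         rx_code = "RX1", icd9_code = "401.9") {
  tibble::tibble(
    patient_id = patient_id, age = as.integer(age), sex = sex,
    date = as.Date(date), rx_type = rx_type, rx_code = rx_code,
    icd9_code = icd9_code)
}

# single-pair model used for parameter-recovery runs: CIRC-META coupling only,
# flat age profile, a small ILL base rate so that every patient contributes at
# least one record (complete stratum denominators), and a modest refill
# probability for diabetes labelling
recovery_model <- function(enrich, pair_rate = 0.2) {
  rates <- stats::setNames(rep(0, 20), icd9_group_labels())
  rates["ILL"] <- 2
  morbidity_model(
    base_rates = rates,
    age_profile = stats::setNames(rep(1, 8), age_class_labels()),
    coupling = tibble::tibble(group_a = "CIRC", group_b = "META",
                              rate = pair_rate, diabetes_mult = enrich),
    diabetes_rate_mult = stats::setNames(rep(1, 20), icd9_group_labels()),
    refill_prob = 0.1)
}

# brute-force O(events x groups^2) pair counter, independent of build_network
brute_force_network <- function(events) {
  node <- list(); edge <- list()
  for (i in seq_len(nrow(events))) {
    gs <- events$groups[[i]]
    for (g in gs) node[[g]] <- (node[[g]] %||% 0) + 1
    u <- sort(unique(gs))
    if (length(u) >= 2) {
      for (a in seq_len(length(u) - 1)) {
        for (b in (a + 1):length(u)) {
          key <- paste(u[a], u[b], sep = "|")
          edge[[key]] <- (edge[[key]] %||% 0) + 1
        }
      }
    }
  }
  list(nodes = unlist(node), edges = unlist(edge))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_events <- function(n_events, n_groups = 6, max_size = 4) {
  groups <- sample(icd9_group_labels(), n_groups)
  tibble::tibble(
    patient_id = sample(sprintf("P%02d", 1:10), n_events, replace = TRUE),
    date = as.Date("2005-01-01") + seq_len(n_events),  # distinct dates
    groups = lapply(seq_len(n_events), function(i)
      sample(groups, sample.int(max_size, 1), replace = TRUE)))
}
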