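test_that("co-prescription events are one per patient-date", {
  rec <- dplyr::bind_rows(
    make_records(icd9_code = "401.9"),                     # CIRC
    make_records(icd9_code = "250.00", rx_code = "RX2"))   # META, same day
  ev <- co_events(rec)
  expect_equal(nrow(ev), 1L)
  expect_setequal(ev$groups[[1]], c("CIRC", "META"))

  apart <- dplyr::bind_rows(
    make_records(), make_records(date = as.Date("2005-07-01")))
  expect_equal(nrow(co_events(apart)), 2L)

  two_patients <- dplyr::bind_rows(
    make_records(patient_id = "P1"), make_records(patient_id = "P2"))
  expect_equal(nrow(co_events(two_patients)), 2L)
  # patient-level co-occurrence collapses a patient's whole history
  expect_equal(nrow(co_events(apart, cooccur = "patient")), 1L)
})

test_that("networks count nodes per record and links once per event, no self-loops", {
  ev1 <- tibble::tibble(patient_id = "P1", date = as.Date("2005-06-01"),
                        groups = list(c("CIRC", "META")))
  net <- build_network(ev1, 1)
  expect_equal(net$nodes$weight[net$nodes$group == "CIRC"], 1)
  expect_equal(net$edges,
               tibble::tibble(group_a = "CIRC", group_b = "META", weight = 1))

  # two same-group prescriptions in one event: node weight 2, no edge
  ev2 <- tibble::tibble(patient_id = "P1", date = as.Date("2005-06-01"),
                        groups = list(c("CIRC", "CIRC")))
  net2 <- build_network(ev2, 1)
  expect_equal(net2$nodes$weight, 2)
  expect_equal(nrow(net2$edges), 0L)

  # three groups in one event: all three unordered pairs, each once
  ev3 <- tibble::tibble(patient_id = "P1", date = as.Date("2005-06-01"),
                        groups = list(c("CIRC", "META", "DIGE")))
  net3 <- build_network(ev3, 1)
  expect_equal(nrow(net3$edges), 3L)
  expect_true(all(net3$edges$weight == 1))

  expect_error(build_network(ev1, 0), "n_patients")
})

test_that("build_network matches a brute-force pair counter on random events", {
  set.seed(7)
  for (i in 1:25) {
    ev <- random_events(sample(50, 1))
    net <- build_network(ev, 10)
    bf <- brute_force_network(ev)
    got_nodes <- stats::setNames(net$nodes$weight, net$nodes$group)
    expect_equal(got_nodes[sort(names(got_nodes))],
                 bf$nodes[sort(names(bf$nodes))])
    got_edges <- stats::setNames(
      net$edges$weight, paste(net$edges$group_a, net$edges$group_b, sep = "|"))
    exp_edges <- bf$edges %||% stats::setNames(numeric(0), character(0))
    expect_equal(got_edges[sort(names(got_edges))],
                 exp_edges[sort(names(exp_edges))])
    # handshake identity
    expect_equal(sum(node_strength(net)$strength), 2 * sum(net$edges$weight))
  }
})

test_that("strengths sum incident link weights and match igraph", {
  ev <- tibble::tibble(
    patient_id = "P1",
    date = as.Date("2005-06-01") + 0:1,
    groups = list(c("CIRC", "META"), c("CIRC", "META", "DIGE")))
  net <- build_network(ev, 1)
  expect_equal(node_strength(net, "CIRC"), 3)  # 2 (META) + 1 (DIGE)
  expect_error(node_strength(net, "RESP"), "unknown group")

  set.seed(19)
  rnet <- build_network(random_events(40), 10)
  ig <- as_igraph(rnet)
  expect_equal(
    stats::setNames(node_strength(rnet)$strength, node_strength(rnet)$group),
    igraph::strength(ig)[node_strength(rnet)$group])
  # isolated node has zero strength
  iso <- build_network(tibble::tibble(patient_id = "P1",
                                      date = as.Date("2005-06-01"),
                                      groups = list("CIRC")), 1)
  expect_equal(node_strength(iso, "CIRC"), 0)
})

test_that("normalization divides all weights by the patient count, coherently", {
  ev <- tibble::tibble(patient_id = sprintf("P%d", 1:5),
                       date = as.Date("2005-06-01"),
                       groups = replicate(5, c("CIRC", "META"),
                                          simplify = FALSE))
  raw <- build_network(ev, 5)
  expect_equal(raw$edges$weight, 5)
  norm <- normalize_network(raw)
  expect_equal(norm$edges$weight, 1)
  expect_error(normalize_network(norm), "already normalized")
  # strength(normalize(net)) == strength(net) / n, both orders
  expect_equal(node_strength(norm)$strength,
               node_strength(raw)$strength / raw$n_patients)
  # n_patients = 1 is the identity
  one <- normalize_network(build_network(ev[1, ], 1))
  expect_equal(one$edges$weight, 1)
})

test_that("duplicating every patient leaves the normalized network unchanged", {
  rec <- simulate_dataset(population_config(n_patients = 60), seed = 23)$records
  twin <- dplyr::mutate(rec, patient_id = paste0(patient_id, "_b"))
  n1 <- dplyr::n_distinct(rec$patient_id)
  net1 <- normalize_network(build_network(co_events(rec), n1))
  net2 <- normalize_network(build_network(co_events(dplyr::bind_rows(rec, twin)),
                                          2 * n1))
  expect_equal(net1$nodes, net2$nodes, tolerance = 1e-12)
  expect_equal(net1$edges, net2$edges, tolerance = 1e-12)
})

test_that("network summary reports per-patient prescriptions sorted, on normalized input", {
  ev <- tibble::tibble(
    patient_id = c("P1", "P2"), date = as.Date("2005-06-01"),
    groups = list(c("CIRC", "CIRC", "META"), c("CIRC")))
  raw <- build_network(ev, 2)
  expect_error(network_summary(raw), "normalized")
  s <- network_summary(normalize_network(raw))
  expect_equal(s$group, c("CIRC", "META"))
  expect_equal(s$gpp_per_patient, c(1.5, 0.5))
  expect_equal(nrow(s), nrow(raw$nodes))
  # empty network
  empty <- normalize_network(build_network(co_events(make_records()[0, ]), 1))
  expect_equal(nrow(network_summary(empty)), 0L)
})

test_that("exports round-trip through GraphML and edge-list TSV", {
  ev <- tibble::tibble(patient_id = "P1", date = as.Date("2005-06-01"),
                       groups = list(c("CIRC", "META")))
  net <- normalize_network(build_network(ev, 4))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(sort(igraph::V(g)$name), c("CIRC", "META"))
  expect_equal(igraph::E(g)$weight, 0.25)
  expect_equal(sort(igraph::V(g)$strength), c(0.25, 0.25))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edgelist")
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$weight, net$edges$weight)

  # empty network still yields parseable GraphML
  empty <- build_network(co_events(make_records()[0, ]), 1)
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, gml2, "graphml")
  expect_equal(igraph::vcount(igraph::read_graph(gml2, format = "graphml")), 0)
  expect_error(export_network(net, tsv, "dot"))
})

test_that("tidy, glance and autoplot expose the network tidily", {
  set.seed(3)
  net <- build_network(random_events(20), 10)
  expect_identical(tidy(net), net$edges)
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(net$edges))
  expect_equal(gl$total_strength, 2 * sum(net$edges$weight))
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
})
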