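# Weighted comorbidity networks over ICD-9 groups.
#
# Node weight = number of prescriptions carrying the group's codes.
# Link weight = number of co-prescription occasions (patient-date events) in
# which the two distinct groups both occur; each unordered pair counts once
# per event, and there are no self-loops. Strength = sum of incident link
# weights. Normalization divides all weights by the stratum's patient count.

#' Group records into co-prescription events
#'
#' The co-occurrence unit: with `cooccur = "visit"` (default) an event is one
#' (patient, date) pair carrying the multiset of groups prescribed that day;
#' with `cooccur = "patient"` all of a patient's records over the window form
#' a single event (link saturation over long windows - offered for
#' comparison, not the default).
#'
#' @param records Validated GPP records.
#' @param cooccur `"visit"` or `"patient"`.
#' @param group_map Mapping table, as from [default_group_map()].
#' @return Tibble with `patient_id`, `date` (first date for patient-level
#'   events) and a `groups` list-column of group labels (with multiplicity).
#' @export
co_events <- function(records, cooccur = c("visit", "patient"),
                      group_map = default_group_map()) {
  cooccur <- match.arg(cooccur)
  grp <- map_code_to_group(records$icd9_code, group_map)
  by <- if (cooccur == "visit") {
    tibble(patient_id = records$patient_id, date = records$date)
  } else {
    tibble(patient_id = records$patient_id)
  }
  sp <- vctrs::vec_split(grp, by)
  ev <- as_tibble(sp$key)
  if (cooccur == "patient") {
    dsp <- vctrs::vec_split(records$date, by)
    ev$date <- as.Date(map_dbl(dsp$val, min), origin = "1970-01-01")
  }
  ev$groups <- sp$val
  select(ev, "patient_id", "date", "groups")
}

new_comorbidity_network <- function(nodes, edges, n_patients, normalized) {
  structure(
    list(nodes = nodes, edges = edges,
         n_patients = n_patients, normalized = normalized),
    class = "comorbidity_network")
}

#' Build a raw-count comorbidity network from co-prescription events
#'
#' @param events Output of [co_events()].
#' @param n_patients Stratum denominator; must be at least the number of
#'   distinct patients appearing in `events`.
#' @return A `comorbidity_network`: `nodes` tibble (`group`, `weight` =
#'   prescription count), `edges` tibble (`group_a < group_b`, `weight` =
#'   co-prescription event count), `n_patients`, `normalized = FALSE`.
#'   Groups with no prescriptions are omitted.
#' @export
build_network <- function(events, n_patients) {
  n_seen <- n_distinct(events$patient_id)
  if (nrow(events) > 0 && n_patients < max(1L, n_seen)) {
    abort("n_patients is smaller than the number of patients in the events")
  }
  len <- lengths(events$groups)
  eg <- tibble(.eid = rep(seq_along(len), len),
               group = as.character(unlist(events$groups)))

  nodes <- eg |>
    count(.data$group, name = "weight") |>
    mutate(weight = as.numeric(.data$weight)) |>
    arrange(.data$group)

  distinct_eg <- distinct(eg, .data$.eid, .data$group)
  edges <- inner_join(distinct_eg, distinct_eg, by = ".eid",
                      relationship = "many-to-many") |>
    filter(.data$group.x < .data$group.y) |>
    count(group_a = .data$group.x, group_b = .data$group.y, name = "weight") |>
    mutate(weight = as.numeric(.data$weight)) |>
    arrange(.data$group_a, .data$group_b)

  new_comorbidity_network(nodes, edges, n_patients, normalized = FALSE)
}

#' Normalize a comorbidity network per patient
#'
#' Divides every node weight and link weight (hence every strength) by the
#' stratum's patient count, making networks comparable across strata.
#'
#' @param net An unnormalized `comorbidity_network`.
#' @return The normalized network.
#' @export
normalize_network <- function(net) {
  stopifnot(inherits(net, "comorbidity_network"))
  if (net$normalized) abort("network is already normalized")
  if (net$n_patients < 1 && nrow(net$nodes) > 0) {
    abort("cannot normalize a non-empty network with zero patients")
  }
  net$nodes$weight <- net$nodes$weight / net$n_patients
  net$edges$weight <- net$edges$weight / net$n_patients
  net$normalized <- TRUE
  net
}

#' Node strength
#'
#' Strength of a group = sum of the weights of its incident links (0 for an
#' isolated node).
#'
#' @param net A `comorbidity_network`.
#' @param group Optional single group label; if given, returns that node's
#'   strength as a number (error if the group is not in the network).
#' @return With `group`: a numeric scalar. Otherwise a tibble
#'   (`group`, `strength`) over all nodes.
#' @export
node_strength <- function(net, group = NULL) {
  stopifnot(inherits(net, "comorbidity_network"))
  incident <- bind_rows(
    select(net$edges, group = "group_a", "weight"),
    select(net$edges, group = "group_b", "weight")) |>
    group_by(.data$group) |>
    summarise(strength = sum(.data$weight), .groups = "drop")
  all_nodes <- net$nodes |>
    select("group") |>
    left_join(incident, by = "group") |>
    mutate(strength = tidyr::replace_na(.data$strength, 0))
  if (is.null(group)) return(all_nodes)
  if (!group %in% all_nodes$group) abort(paste0("unknown group: ", group))
  all_nodes$strength[all_nodes$group == group]
}

#' Per-node summary of a normalized network
#'
#' One row per group: mean prescriptions per patient (the normalized node
#' weight, the quantity node sizes encode in the network figures) and
#' strength (the comorbidity measure node colors encode), sorted by node
#' weight descending.
#'
#' @param net A normalized `comorbidity_network`.
#' @return Tibble (`group`, `gpp_per_patient`, `strength`).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "comorbidity_network"))
  if (!net$normalized) abort("network_summary() requires a normalized network")
  net$nodes |>
    rename(gpp_per_patient = "weight") |>
    left_join(node_strength(net), by = "group") |>
    arrange(desc(.data$gpp_per_patient))
}

#' Convert to an igraph object
#'
#' Undirected weighted graph; vertex attributes `weight` and `strength`,
#' edge attribute `weight`.
#'
#' @param net A `comorbidity_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "comorbidity_network"))
  vertices <- net$nodes |>
    left_join(node_strength(net), by = "group") |>
    select(name = "group", "weight", "strength")
  edges <- select(net$edges, from = "group_a", to = "group_b", "weight")
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Export a comorbidity network
#'
#' GraphML (vertex attributes `weight`, `strength`; edge attribute `weight`)
#' or a plain edge-list TSV `group_a group_b weight`. Weights are serialized
#' with 6 significant digits.
#'
#' @param net A `comorbidity_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  rounded <- net
  rounded$nodes$weight <- signif(rounded$nodes$weight, 6)
  rounded$edges$weight <- signif(rounded$edges$weight, 6)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(rounded), path, format = "graphml")
  } else {
    readr::write_tsv(rounded$edges, path)
  }
  invisible(path)
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat(sprintf(
    "<comorbidity_network> %d groups, %d links, %d patients (%s)\n",
    nrow(x$nodes), nrow(x$edges), x$n_patients,
    if (x$normalized) "per-patient normalized" else "raw counts"))
  if (nrow(x$nodes)) {
    top <- head(arrange(x$nodes, desc(.data$weight)), 5)
    cat("  top nodes:",
        paste(sprintf("%s=%.3g", top$group, top$weight), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tidy a comorbidity network into its edge table
#'
#' @param x A `comorbidity_network`.
#' @param ... Unused.
#' @return The edge tibble (`group_a`, `group_b`, `weight`).
#' @export
tidy.comorbidity_network <- function(x, ...) x$edges

#' One-row summary of a comorbidity network
#'
#' @param x A `comorbidity_network`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `n_patients`, `total_weight` (sum of
#'   node weights), `total_strength` (sum of node strengths, equal to twice
#'   the sum of link weights), `normalized`.
#' @export
glance.comorbidity_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_patients = x$n_patients,
    total_weight = sum(x$nodes$weight),
    total_strength = 2 * sum(x$edges$weight),
    normalized = x$normalized)
}

#' Plot a comorbidity network
#'
#' Circular layout; point size encodes node weight (prescriptions, per
#' patient if normalized), point color encodes strength, segment width the
#' link weight.
#'
#' @param object A `comorbidity_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comorbidity_network <- function(object, ...) {
  nodes <- object$nodes |>
    left_join(node_strength(object), by = "group") |>
    mutate(angle = 2 * pi * (row_number() - 1) / n(),
           x = cos(.data$angle), y = sin(.data$angle))
  edges <- object$edges |>
    left_join(select(nodes, "group", xa = "x", ya = "y"),
              by = c(group_a = "group")) |>
    left_join(select(nodes, "group", xb = "x", yb = "y"),
              by = c(group_b = "group"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      color = "grey60", alpha = 0.7) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$weight,
                   color = .data$strength)) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                   label = .data$group), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "GPP", color = "strength", linewidth = "link weight")
}
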