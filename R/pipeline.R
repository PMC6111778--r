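# End-to-end pipeline: simulate (or read) -> validate -> summarize ->
# stratify -> networks -> age curves -> D/ND ratios, written to an output
# directory with a checksummed manifest. Deterministic given the seed.

#' Run the full comorbidity-network pipeline
#'
#' Generates a synthetic dataset (or reads one from `input`), validates it,
#' writes the prescription-type and group-by-type summary tables, exports the
#' per-age-class comorbidity networks for a focus sex (GraphML + edge-list
#' TSV, drug prescriptions, diabetic and non-diabetic strata), writes the
#' morbidity/comorbidity age curves and the META-anchored D/ND rate-ratio
#' table, and finishes with `manifest.json` listing every artifact with its
#' MD5 checksum and the configuration used. Progress goes to stderr; results
#' only to files. Identical seeds give byte-identical tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param input Optional CSV of GPP records; exactly one of `input` and
#'   `config` may be supplied (a generator config conflicts with an input
#'   file).
#' @param config A [population_config()] for the generator (default: 2000
#'   patients at the reference marginals).
#' @param model A [morbidity_model()].
#' @param window Closed observation window.
#' @param window_years Effective window years for per-patient-per-year rates.
#' @param sex_focus Sex for the stratified network/curve/ratio outputs.
#' @param ratio_groups Groups profiled against META in the ratio table.
#' @param cooccur Co-occurrence unit (`"visit"` or `"patient"`).
#' @param level Confidence level for ratio intervals.
#' @param seed Integer seed governing all randomness.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(out_dir,
                         input = NULL,
                         config = NULL,
                         model = morbidity_model(),
                         window = gpp_window(),
                         window_years = 11,
                         sex_focus = "M",
                         ratio_groups = c("CIRC", "RESP", "DIGE", "GEN"),
                         cooccur = "visit",
                         level = 0.95,
                         seed = 42L) {
  if (!is.null(input) && !is.null(config)) {
    abort("supply either an input file or a generator config, not both")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    message("wrote ", path)
  }

  if (is.null(input)) {
    config <- config %||% population_config(n_patients = 2000)
    message("simulating ", config$n_patients, " patients (seed ", seed, ")")
    ds <- simulate_dataset(config, model, window = window, seed = seed)
    records <- validate_gpp(ds$records, window = window)
    emit("records.csv", function(p) write_gpp(records, p))
  } else {
    message("reading ", input)
    records <- read_gpp(input, window = window)
  }
  rep <- validation_report(records)
  n_patients <- n_distinct(records$patient_id)
  message(rep$n_kept, " records kept, ", rep$n_rejected, " rejected, ",
          n_patients, " patients")

  emit("type_summary.csv", function(p)
    readr::write_csv(summarize_by_type(records, n_patients, window_years), p))
  emit("group_type_summary.csv", function(p)
    readr::write_csv(summarize_group_by_type(records), p))

  # stratified networks for the focus sex, drug prescriptions, by age x D/ND
  for (db in c("D", "ND")) {
    strata <- stratify(records, by = "age_class", sex = sex_focus,
                       diabetes = db, rx_type = "Drug")
    for (i in seq_len(nrow(strata))) {
      net <- normalize_network(build_network(
        co_events(strata$records[[i]], cooccur), strata$n_patients[i]))
      tag <- gsub("[^0-9]+", "-", strata$age_class[i])
      tag <- paste0(sex_focus, "_", db, "_age", sub("-$", "", tag))
      emit(paste0("network_", tag, ".graphml"), function(p)
        export_network(net, p, "graphml"))
      emit(paste0("network_", tag, ".tsv"), function(p)
        export_network(net, p, "edgelist"))
    }
  }

  # morbidity/comorbidity age curves for all / D / ND
  curves <- purrr::map(c(all = "all", D = "D", ND = "ND"), function(db) {
    s <- stratify(records, by = "age_class", sex = sex_focus,
                  diabetes = db, rx_type = "Drug")
    bind_rows(
      mutate(morbidity_curve(s), measure = "morbidity"),
      mutate(comorbidity_curve(s, cooccur), measure = "comorbidity"))
  }) |>
    purrr::list_rbind(names_to = "population") |>
    select("measure", "population", "age_class", "n_patients", "value")
  emit("age_curves.csv", function(p) readr::write_csv(curves, p))

  # META-anchored D/ND ratio table, pooled over the focus sex's age classes
  sd <- stratify(records, by = "sex", sex = sex_focus,
                 diabetes = "D", rx_type = "Drug")
  snd <- stratify(records, by = "sex", sex = sex_focus,
                  diabetes = "ND", rx_type = "Drug")
  if (nrow(sd) && nrow(snd)) {
    ratios <- meta_coprescription_profile(sd, snd, groups = ratio_groups,
                                          cooccur = cooccur) |>
      dn_ratio_profile(level = level)
    emit("dn_ratios.csv", function(p) readr::write_csv(ratios, p))
  } else {
    warn("no diabetic or no non-diabetic stratum; skipping ratio table")
  }

  manifest <- list(
    seed = seed,
    window = as.character(window),
    window_years = window_years,
    sex_focus = sex_focus,
    cooccur = cooccur,
    level = level,
    n_patients = n_patients,
    validation = list(n_input = rep$n_input, n_rejected = rep$n_rejected),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("wrote ", file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
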