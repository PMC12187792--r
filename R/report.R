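# End-to-end workflow: element-by-element report and reproducible
# artifact writer.

#' Element-by-element accumulation report
#'
#' Chains the survey summary, the accumulation indices and the cerium
#' anomaly into one table per element: median BcF and EF per horizon, the
#' enrichment class of the median humus EF, and the
#' accumulated/intermediate/excluder verdict (see
#' [accumulation_verdict()]).
#'
#' @param study A list with `frond` and the substrate tables `humus`,
#'   `topsoil`, `subsoil` (e.g. from [generate_study()] or assembled from
#'   [read_concentration_table()] calls).
#' @param config An [analysis_config()].
#' @return A tibble with one row per element: `element`, `verdict`,
#'   `median_frond_mg_kg`, `bcf_humus`, `bcf_topsoil`, `bcf_subsoil`,
#'   `ef_humus`, `ef_topsoil`, `ef_subsoil`, `ef_class_humus`.
#' @export
accumulation_report <- function(study, config = analysis_config()) {
  frond <- aggregate_replicates(study$frond, config$replicate_rule)
  substrates <- study[intersect(.horizons, names(study))]
  idx <- compute_indices(frond, substrates)
  med <- median_index(idx)
  verdict <- accumulation_verdict(
    med,
    bcf_excluder = config$bcf_excluder,
    ef_accumulated = config$ef_accumulated
  )
  med_wide <- tidyr::pivot_wider(
    dplyr::mutate(med,
      name = paste0(tolower(.data$index_kind), "_", .data$horizon)
    ),
    id_cols = "element", names_from = "name", values_from = "value"
  )
  frond_med <- dplyr::summarise(
    dplyr::group_by(frond, .data$element),
    median_frond_mg_kg = median(.data$value_mg_kg, na.rm = TRUE),
    .groups = "drop"
  )
  ef_hum <- dplyr::select(
    dplyr::filter(
      med, .data$index_kind == "EF", .data$horizon == "humus"
    ),
    "element",
    ef_class_humus = "ef_class"
  )
  out <- dplyr::left_join(
    dplyr::select(verdict, "element", "verdict"),
    frond_med,
    by = "element"
  )
  out <- dplyr::left_join(out, med_wide, by = "element")
  dplyr::left_join(out, ef_hum, by = "element")
}

#' Run the full pipeline and write reproducible artifacts
#'
#' Executes the whole analysis on a study (synthetic by default) and
#' writes every artifact as CSV/JSON into `output_dir`: site factors,
#' concentration tables, the per-element summary battery (in the
#' conventional column order Min, Max, Mean, SD, RSD, I.Q, Median, III.Q,
#' MAD), per-site indices and their medians, REE patterns with anomaly
#' calls, stoichiometry, the correlation screen against site factors, the
#' two dendrograms (Newick plus JSON merge lists), the element report and
#' a run manifest (package version, seed, configuration and its hash,
#' file list). Artifacts are a pure function of (study, config): the same
#' inputs give byte-identical files.
#'
#' @param study See [accumulation_report()]; defaults to a synthetic
#'   study generated with `synth_config(seed = config$seed)`.
#' @param config An [analysis_config()].
#' @param output_dir Directory to create/fill.
#' @return Invisibly, a list of computed results (`summary`, `indices`,
#'   `median_indices`, `ree`, `stoichiometry`, `screen`,
#'   `element_tree`, `site_tree`, `report`, `manifest`).
#' @export
run_pipeline <- function(output_dir, study = NULL,
                         config = analysis_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(study)) {
    study <- generate_study(synth_config(seed = config$seed))
  }
  frond <- aggregate_replicates(study$frond, config$replicate_rule)
  substrates <- study[intersect(.horizons, names(study))]

  summary <- summarize_elements(frond, config$quartile_type)
  idx <- compute_indices(frond, substrates)
  med <- median_index(idx)
  ree <- ce_anomaly_table(frond, config$ree_reference, config$anomaly_band)
  stoich <- tryCatch(
    stoichiometry_table(frond, config$np_low, config$np_high),
    error = function(e) NULL
  )
  report <- accumulation_report(study, config)

  # correlation screen: frond element contents vs. site factors
  frond_wide <- tidyr::pivot_wider(frond,
    id_cols = "site_id", names_from = "element", values_from = "value_mg_kg"
  )
  sites <- bedrock_indicators(study$sites)
  frame <- dplyr::left_join(frond_wide, sites, by = "site_id")
  predictors <- intersect(
    c(
      "elevation_m", "evaporation_mid", "humus_pH", "topsoil_pH",
      paste0("bedrock_", .bedrock_classes)
    ),
    names(frame)
  )
  screen <- spearman_screen(
    frame,
    targets = setdiff(names(frond_wide), "site_id"),
    predictors = predictors,
    adjust = config$p_adjust
  )

  etree <- cluster_elements(study$frond,
    median_of_logs = config$median_of_logs
  )
  stree <- cluster_sites(study$frond, median_of_logs = config$median_of_logs)

  p <- function(f) file.path(output_dir, f)
  readr::write_csv(study$sites, p("sites.csv"), progress = FALSE)
  write_concentration_table(study$frond, p("frond.csv"))
  for (h in names(substrates)) {
    write_concentration_table(substrates[[h]], p(paste0(h, ".csv")))
  }
  table2_order <- dplyr::select(summary,
    "element", "n", Min = "min", Max = "max", Mean = "mean", SD = "sd",
    `RSD (%)` = "rsd_pct", I.Q = "q1", Median = "median", III.Q = "q3",
    MAD = "mad"
  )
  readr::write_csv(table2_order, p("summary.csv"), progress = FALSE)
  readr::write_csv(idx, p("indices.csv"), progress = FALSE)
  readr::write_csv(med, p("median_indices.csv"), progress = FALSE)
  readr::write_csv(ree, p("ree_patterns.csv"), progress = FALSE)
  if (!is.null(stoich)) {
    readr::write_csv(stoich, p("stoichiometry.csv"), progress = FALSE)
  }
  readr::write_csv(screen, p("correlations.csv"), progress = FALSE)
  readr::write_csv(report, p("report.csv"), progress = FALSE)
  write_newick(etree, p("elements.nwk"))
  write_newick(stree, p("sites.nwk"))
  jsonlite::write_json(tidy(etree), p("elements_tree.json"), digits = NA)
  jsonlite::write_json(tidy(stree), p("sites_tree.json"), digits = NA)
  jsonlite::write_json(report, p("report.json"), digits = NA)

  manifest <- list(
    package = "phytoaccum",
    version = as.character(utils::packageVersion("phytoaccum")),
    seed = config$seed,
    config = unclass(config),
    config_hash = .config_hash(config),
    files = sort(list.files(output_dir))
  )
  jsonlite::write_json(manifest, p("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    summary = summary, indices = idx, median_indices = med, ree = ree,
    stoichiometry = stoich, screen = screen, element_tree = etree,
    site_tree = stree, report = report, manifest = manifest
  ))
}
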