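# End-to-end orchestration: ingest -> deduplicate -> role-filter ->
# descriptive tables -> disproportionality scan -> bubble coordinates,
# with provenance logging at every exclusion step.

log_msg <- function(level, threshold, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[threshold]]) {
    message("[", toupper(level), "] ", ...)
  }
}

#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis. `NULL` entries fall back to
#' the defaults documented per argument. A YAML file with the same field
#' names can be loaded with [pipeline_config_from_yaml()].
#'
#' @param input Path of the raw report extract (CSV/TSV).
#' @param drug Target drug name.
#' @param role Role defining the curated case series
#'   (default `"PRIMARY_SUSPECT"`).
#' @param col_map Optional column map (named list or YAML path), see
#'   [read_reports()].
#' @param pt_soc Optional path of a PT-to-SOC mapping TSV.
#' @param min_cases,chi2_threshold,prr_threshold Evans thresholds, see
#'   [signal_criteria()].
#' @param alpha CI significance level.
#' @param corrected Use Yates-corrected chi-square.
#' @param out_dir Output directory for the artifact files.
#' @param seed Seed used by the `simulate` entry point.
#' @param log_level `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, drug, role = "PRIMARY_SUSPECT",
                            col_map = NULL, pt_soc = NULL,
                            min_cases = 3, chi2_threshold = 4,
                            prr_threshold = 2, alpha = 0.05,
                            corrected = TRUE, out_dir = "pvsignal_out",
                            seed = 1L, log_level = "info") {
  stopifnot(alpha > 0, alpha < 1, log_level %in% c("debug", "info", "warn", "quiet"))
  structure(
    list(input = input, drug = drug, role = role, col_map = col_map,
         pt_soc = pt_soc, min_cases = min_cases,
         chi2_threshold = chi2_threshold, prr_threshold = prr_threshold,
         alpha = alpha, corrected = corrected, out_dir = out_dir,
         seed = as.integer(seed), log_level = log_level),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full signal-detection pipeline
#'
#' Reads the extract, deduplicates by case id, derives the curated case
#' series (reports where the target drug carries the configured role), and
#' writes: the curated database (`curated.csv`), a provenance summary
#' (`provenance.json`), the descriptive distribution tables
#' (`distribution_<dimension>.tsv` and a combined `descriptive.json`), the
#' top-30 term table (`top_terms.tsv`), a SOC occurrence table
#' (`soc_table.tsv`), the full signal table (`signals.tsv`) and the
#' bubble-plot coordinates (`bubble.tsv`). The disproportionality scan runs
#' against the complete deduplicated database, so the comparator background
#' is every report not in the curated series. Identical inputs and
#' configuration give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory objects (`db_full`,
#'   `db_curated`, `signals`, `descriptive`, `bubble`, `provenance`) and
#'   `paths` of the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  lvl <- config$log_level
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  db <- read_reports(config$input, col_map = config$col_map)
  log_msg("info", lvl, "read ", db$provenance$rows_read, " rows -> ",
          db$provenance$reports_read, " report versions")
  db <- deduplicate(db)
  log_msg("info", lvl, "deduplicated: ", db$provenance$duplicates_removed,
          " duplicate versions removed, ", n_reports(db), " reports kept")
  curated <- filter_by_role(db, config$drug, config$role)
  log_msg("info", lvl, "role filter (", config$role, "): ",
          curated$provenance$role_excluded, " reports excluded, ",
          n_reports(curated), " curated cases")
  if (n_reports(curated) == 0) {
    stop("role filter: no reports with ", config$drug, " as ", config$role,
         call. = FALSE)
  }

  mapping <- if (!is.null(config$pt_soc)) load_pt_soc(config$pt_soc) else NULL
  criteria <- signal_criteria(config$min_cases, config$chi2_threshold,
                              config$prr_threshold)

  dims <- setdiff(DIMENSIONS, "role")
  descr <- lapply(dims, function(d) distribution(curated, d))
  names(descr) <- dims
  descr$role <- distribution(db, "role", drug = config$drug)
  tops <- top_terms(curated, 30)
  soc_tab <- soc_aggregate(pt_occurrences(curated), mapping)

  signals <- signal_scan(db, config$drug, criteria, role = config$role,
                         alpha = config$alpha, corrected = config$corrected,
                         mapping = mapping)
  log_msg("info", lvl, "signal scan: ", nrow(signals), " PTs, ",
          sum(signals$is_signal), " classified as signals")
  bubble <- bubble_coordinates(signals)

  paths <- list(
    curated = file.path(config$out_dir, "curated.csv"),
    provenance = file.path(config$out_dir, "provenance.json"),
    descriptive = file.path(config$out_dir, "descriptive.json"),
    top_terms = file.path(config$out_dir, "top_terms.tsv"),
    soc_table = file.path(config$out_dir, "soc_table.tsv"),
    signals = file.path(config$out_dir, "signals.tsv"),
    bubble = file.path(config$out_dir, "bubble.tsv")
  )
  write_reports(curated, paths$curated)
  jsonlite::write_json(curated$provenance, paths$provenance, auto_unbox = TRUE)
  jsonlite::write_json(descr, paths$descriptive, dataframe = "rows", digits = NA)
  readr::write_tsv(tops, paths$top_terms)
  readr::write_tsv(soc_tab, paths$soc_table)
  readr::write_tsv(signals, paths$signals)
  readr::write_tsv(bubble, paths$bubble)
  for (d in dims) {
    p <- file.path(config$out_dir, paste0("distribution_", d, ".tsv"))
    readr::write_tsv(descr[[d]], p)
    paths[[paste0("distribution_", d)]] <- p
  }
  log_msg("info", lvl, "artifacts written to ", config$out_dir)

  invisible(list(db_full = db, db_curated = curated, signals = signals,
                 descriptive = descr, top_terms = tops, soc_table = soc_tab,
                 bubble = bubble, provenance = curated$provenance,
                 paths = paths))
}
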