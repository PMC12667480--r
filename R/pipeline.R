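#' Run the full TLS pipeline on a simulated cohort
#'
#' End-to-end, deterministic analysis: simulate a cohort, QC-filter and
#' log-normalize each sample, assign cell types by the marker panel, call
#' TLS regions by DBSCAN, assign TLS/nTLS membership, validate TLS marker
#' genes, classify TLS maturity, run TLS-vs-nTLS differential expression,
#' stratify samples at the median TLS score, and compare survival between
#' the high and low groups by Kaplan-Meier / log-rank. All tables are
#' written under `out_dir` as plain CSV/TSV; a fixed seed yields
#' byte-identical outputs.
#'
#' The QC thresholds default to values suited to the simulator's compact
#' gene universe (about 160 genes); for real panels use
#' [qc_thresholds()]'s defaults.
#'
#' @param out_dir Output directory (created if missing).
#' @param params Simulation parameters.
#' @param n_samples Cohort size.
#' @param seed Seed for the whole run.
#' @param detection [detection_params()] for TLS calling.
#' @param qc [qc_thresholds()] applied per sample.
#' @param score_criterion Median-split statistic for the TLS score groups.
#' @param de_preset Retention preset for TLS-vs-nTLS differential
#'   expression.
#' @return Invisibly, a list with the in-memory results (`cells`,
#'   `regions`, `score_report`, `validation`, `de`, `survival`,
#'   `logrank`, `km`) and `files`, the written paths.
#' @export
run_pipeline <- function(out_dir,
                         params = sim_params(),
                         n_samples = 6,
                         seed = params$seed,
                         detection = detection_params(),
                         qc = qc_thresholds(min_genes = 10, max_genes = 160,
                                            max_mito_fraction = 0.25),
                         score_criterion = c("cell_count", "cumulative_area"),
                         de_preset = "go-deg") {
  score_criterion <- arg_match(score_criterion)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params$seed <- seed

  cohort <- simulate_cohort(params, n_samples, seed = seed)

  cells_list <- list(); norm_list <- list()
  for (s in names(cohort$samples)) {
    sim <- cohort$samples[[s]]
    filt <- qc_filter(sim$counts, sim$cells, thresholds = qc)
    norm <- lognormalize(filt$counts)
    cells_list[[s]] <- assign_cell_types(filt$cells, norm)
    norm_list[[s]] <- norm
  }
  cells <- bind_rows(cells_list)
  norm <- do.call(rbind, norm_list)

  regions <- call_tls(cells, detection)
  cells <- assign_tls_membership(cells, regions)

  validation <- if (nrow(regions) > 0L && any(is.na(cells$tls_id)) &&
                    any(!is.na(cells$tls_id))) {
    validate_tls_markers(norm, cells)
  } else NULL

  if (nrow(regions) >= 2L) {
    regions <- classify_maturity(regions, norm)
  }

  de <- if (!is.null(validation)) {
    differential_expression(norm[cells$cell_id, , drop = FALSE],
                            !is.na(cells$tls_id), preset = de_preset)
  } else NULL

  report <- tls_score_report(cells, regions, criterion = score_criterion)
  survival <- cohort$survival
  survival$group <- report$group[match(survival$sample_id, report$sample_id)]

  high <- survival[survival$group == "high", , drop = FALSE]
  low <- survival[survival$group == "low", , drop = FALSE]
  logrank <- NULL; km <- NULL
  if (nrow(high) > 0L && nrow(low) > 0L &&
      sum(survival$event) >= 1L) {
    logrank <- logrank_test(high, low)
    km <- list(high = km_curve(high), low = km_curve(low))
  }

  files <- write_pipeline_outputs(out_dir, cells, regions, report,
                                  validation, de, survival, km, logrank)
  invisible(list(cells = cells, regions = regions, score_report = report,
                 validation = validation, de = de, survival = survival,
                 logrank = logrank, km = km, files = files))
}

write_pipeline_outputs <- function(out_dir, cells, regions, report,
                                   validation, de, survival, km, logrank) {
  path <- function(f) file.path(out_dir, f)
  files <- c(
    cells = path("cells.tsv"),
    regions = path("tls_regions.csv"),
    score_report = path("tls_score_report.csv"),
    survival = path("survival_groups.csv")
  )
  write_cell_labels(cells, files[["cells"]])
  write_tls_regions(regions, files[["regions"]])
  readr::write_csv(report, files[["score_report"]], progress = FALSE)
  write_survival(survival, files[["survival"]])
  if (!is.null(validation)) {
    files[["validation"]] <- path("tls_marker_validation.csv")
    readr::write_csv(validation, files[["validation"]], progress = FALSE)
  }
  if (!is.null(de)) {
    files[["de"]] <- path("de_tls_vs_ntls.csv")
    readr::write_csv(as_tibble(de), files[["de"]], progress = FALSE)
  }
  if (!is.null(km)) {
    files[["km_high"]] <- path("km_high.csv")
    files[["km_low"]] <- path("km_low.csv")
    readr::write_csv(tidy(km$high), files[["km_high"]], progress = FALSE)
    readr::write_csv(tidy(km$low), files[["km_low"]], progress = FALSE)
  }
  if (!is.null(logrank)) {
    files[["logrank"]] <- path("logrank.json")
    writeLines(jsonlite::toJSON(list(
      chi2 = logrank$chi2, p = logrank$p,
      observed = as.list(logrank$observed),
      expected = as.list(logrank$expected),
      n = as.list(logrank$n)
    ), auto_unbox = TRUE, digits = NA), files[["logrank"]])
  }
  files
}

#' Read a flat key:value configuration file
#'
#' YAML subset used by the command-line interface: one `key: value` pair
#' per line; keys matching [sim_params()], [detection_params()] or
#' [qc_thresholds()] arguments override the defaults.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("File not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_format(sprintf("%s: expected key: value pairs.", path))
  cfg
}
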