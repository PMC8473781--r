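#' Run the full DFC state pipeline
#'
#' Executes, in order: per-subject tapered sliding-window connectivity,
#' two-stage state clustering, per-subject state metrics, the group occupancy
#' table, group t tests and clinical correlations, and nested-CV LSVM
#' classification (with an optional permutation test). One master seed governs
#' every stochastic stage through [stage_seed()]; reruns with the same config
#' and inputs are identical. All tables are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param manifest a cohort manifest (see [read_manifest()]); `series_path`
#'   entries must be readable, or pass `timeseries` directly.
#' @param out_dir output directory for result tables (default: a tempdir
#'   subfolder).
#' @param timeseries optional named list of [roi_timeseries()] keyed by
#'   subject id, bypassing file reads (used with simulated cohorts).
#' @param run_permutation run the permutation test (default FALSE; it reruns
#'   the nested CV `n_permutations` times).
#' @return a `pipeline_result` list: fitted `model`, `metrics`, `occupancy`,
#'   `group_tests`, `correlations`, `classification`, `permutation` (or NULL),
#'   `paths` of written tables, and the resolved `config`.
#' @export
run_pipeline <- function(config, manifest, out_dir = NULL, timeseries = NULL,
                         run_permutation = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- as_cohort_manifest(as.data.frame(manifest))
  out_dir <- out_dir %||% file.path(tempdir(), "dfcstates_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dfc_log("pipeline", sprintf("%d subjects, seed %d, out_dir %s",
                              nrow(manifest), config$seed, out_dir))

  # stage 1: windowed connectivity
  dfc_list <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    ts <- if (!is.null(timeseries)) {
      if (is.null(timeseries[[id]]))
        stop("stage dfc, subject ", id, ": no time series supplied")
      timeseries[[id]]
    } else {
      if (!file.exists(manifest$series_path[i]))
        stop("stage dfc, subject ", id, ": file not found: ",
             manifest$series_path[i])
      read_timeseries(manifest$series_path[i], subject_id = id)
    }
    subject_dfc(ts, config$window)
  })

  # stage 2: state clustering (cluster seed derived from the master seed)
  cl <- config$cluster
  cl$seed <- stage_seed(config$seed, "cluster")
  model <- fit_dfc_states(dfc_list, cl)

  # stage 3: metrics + occupancy
  metrics <- state_metrics(model)
  occupancy <- group_occupancy_table(metrics, manifest)

  # stage 4: group statistics and clinical correlations
  group_tests <- group_metric_tests(metrics, manifest)
  have_clin <- c("cipe_total", "ielt_minutes")[
    vapply(c("cipe_total", "ielt_minutes"),
           function(cv) any(!is.na(manifest[[cv]])), TRUE)]
  correlations <- if (length(have_clin))
    metric_clinical_correlations(metrics, manifest, clinical = have_clin)
  else NULL

  # stage 5: classification
  cf <- config$classify
  cf$seed <- stage_seed(config$seed, "classify")
  features <- build_feature_matrix(metrics, manifest)
  classification <- nested_cv(features, cf)
  permutation <- if (run_permutation)
    permutation_test(features, cf, observed = classification) else NULL

  paths <- list(
    metrics = file.path(out_dir, "state_metrics.csv"),
    occupancy = file.path(out_dir, "occupancy_table.csv"),
    group_tests = file.path(out_dir, "group_tests.csv"),
    correlations = file.path(out_dir, "clinical_correlations.csv"),
    centroids = file.path(out_dir, "state_centroids.tsv"),
    assignments = file.path(out_dir, "state_assignments.csv"),
    classification = file.path(out_dir, "classification_report.json"),
    config = file.path(out_dir, "config.yaml"))

  write_metrics(metrics, manifest, paths$metrics)
  occ_df <- data.frame(group = rownames(occupancy$counts), occupancy$counts,
                       total = occupancy$group_totals)
  utils::write.csv(occ_df, paths$occupancy, row.names = FALSE)
  utils::write.csv(group_tests, paths$group_tests, row.names = FALSE)
  if (!is.null(correlations))
    utils::write.csv(correlations, paths$correlations, row.names = FALSE)
  utils::write.table(model$centroids, paths$centroids, sep = "\t",
                     row.names = TRUE, col.names = NA, quote = FALSE)
  assign_df <- do.call(rbind, lapply(names(model$assignments), function(id)
    data.frame(subject_id = id,
               window_index = seq_along(model$assignments[[id]]) - 1L,
               state = model$assignments[[id]])))
  utils::write.csv(assign_df, paths$assignments, row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = classification$accuracy,
         sensitivity = classification$sensitivity,
         specificity = classification$specificity, auc = classification$auc,
         decision_scores = stats::setNames(as.list(classification$decision_scores),
                                           classification$subject_id),
         permutation_p = if (!is.null(permutation))
           list(accuracy = permutation$p_accuracy, auc = permutation$p_auc)),
    paths$classification, auto_unbox = TRUE, digits = NA)
  write_config(config, paths$config)

  dfc_log("pipeline", "done; k = ", model$k, ", accuracy = ",
          sprintf("%.2f%%", classification$accuracy))
  structure(list(model = model, metrics = metrics, occupancy = occupancy,
                 group_tests = group_tests, correlations = correlations,
                 classification = classification, permutation = permutation,
                 paths = paths, config = config, dfc = dfc_list),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("DFC pipeline result\n")
  print(x$model)
  print(x$occupancy)
  print(x$classification)
  invisible(x)
}
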