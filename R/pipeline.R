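#' Build a pipeline configuration
#'
#' Collects every stage's parameters with their defaults filled in, so the
#' resolved configuration written alongside the outputs regenerates the run
#' exactly.
#'
#' @param simulation A [simulation_config()] plus `n_subjects`, or `NULL`
#'   when `input_files` are given.
#' @param input_files Character vector of recording files ([read_eeg()]
#'   formats) used instead of simulation.
#' @param n_subjects Number of simulated subjects.
#' @param low_hz,high_hz Band-pass edges.
#' @param target_fs Decimation target (equal to the data's rate = no-op).
#' @param k_range Group-level candidate class counts.
#' @param individual_k Per-subject class count at clustering stage one.
#' @param n_restarts,tol Clustering settings.
#' @param window_half_size,besag_factor Smoothing parameters.
#' @param alpha Significance level for clinical correlations.
#' @param clinical Optional clinical table (see [correlate_with_clinical()]).
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_files = NULL, n_subjects = 10,
                            low_hz = 1, high_hz = 40, target_fs = NULL,
                            k_range = 2:8, individual_k = 6,
                            n_restarts = 20, tol = 1e-6,
                            window_half_size = 3, besag_factor = 10,
                            alpha = 0.01, clinical = NULL, seed = 1) {
  structure(
    list(simulation = simulation, input_files = input_files,
         n_subjects = n_subjects, low_hz = low_hz, high_hz = high_hz,
         target_fs = target_fs, k_range = k_range,
         individual_k = individual_k, n_restarts = n_restarts, tol = tol,
         window_half_size = window_half_size, besag_factor = besag_factor,
         alpha = alpha, clinical = clinical, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full microstate pipeline
#'
#' Simulate (or load) -> preprocess -> two-level clustering with
#' meta-criterion K selection -> backfit + temporal smoothing -> temporal
#' metrics and GEV -> group statistics (and clinical correlations when a
#' clinical table is supplied). With `out_dir` set, writes the global model
#' maps, the meta-criterion table, per-subject segmentations, the metrics
#' table, the statistics tables, the resolved configuration (JSON) and a run
#' log with all seeds; every output is regenerable from the resolved config
#' alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `pipeline_result`: `fit` (the [two_level_cluster()]
#'   result), `segmentations`, `metrics`, `group_tests`,
#'   `clinical_correlations` (or `NULL`), `truth` (per-subject ground truth
#'   for simulated input, else `NULL`), and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(sprintf("run_pipeline seed=%s", config$seed))
  stage <- function(msg) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0, msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  truth <- NULL
  if (!is.null(config$input_files)) {
    stage(sprintf("loading %d recordings", length(config$input_files)))
    recs <- lapply(config$input_files, read_eeg)
  } else {
    stage(sprintf("simulating %d subjects (%d ch, %g Hz, %g s, K=%d, snr=%g)",
                  config$n_subjects, config$simulation$n_channels,
                  config$simulation$fs, config$simulation$duration_s,
                  config$simulation$K_true, config$simulation$snr))
    cohort <- simulate_cohort(config$n_subjects, config$simulation,
                              base_seed = config$seed)
    recs <- lapply(cohort$subjects, `[[`, "recording")
    truth <- list(templates = cohort$templates,
                  subjects = lapply(cohort$subjects, `[[`, "truth"))
  }

  stage("preprocessing (band-pass, decimation, average reference)")
  recs <- lapply(recs, function(r) {
    r <- bandpass_filter(r, config$low_hz, config$high_hz)
    if (!is.null(config$target_fs)) r <- downsample(r, config$target_fs)
    average_reference(r)
  })

  stage(sprintf("two-level clustering (individual K=%d, group k_range=%s)",
                config$individual_k,
                paste(range(config$k_range), collapse = "-")))
  fit <- two_level_cluster(recs, k_range = config$k_range,
                           individual_k = config$individual_k,
                           n_restarts = config$n_restarts, tol = config$tol,
                           seed = config$seed)
  stage(sprintf("selected K* = %d (group GEV on pooled maps = %.3f)",
                fit$model$K, fit$model$gev_total))

  stage("backfitting, smoothing, temporal metrics")
  segs <- vector("list", length(recs))
  metrics <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    ss <- segment_subject(recs[[i]], fit$model,
                          window_half_size = config$window_half_size,
                          besag_factor = config$besag_factor)
    ss$metrics$gev_total <- ss$gev$gev_total
    segs[[i]] <- ss$segmentation
    metrics[[i]] <- ss$metrics
  }
  names(segs) <- vapply(seq_along(recs), function(i)
    as.character(recs[[i]]$subject %||% sprintf("subject%02d", i)), character(1))
  metrics <- do.call(rbind, metrics)

  group_tests <- NULL
  if ("group" %in% names(metrics) && length(unique(metrics$group)) == 2L) {
    stage("group t-tests with FDR correction")
    group_tests <- group_ttests(metrics)
  }
  clin_cor <- NULL
  if (!is.null(config$clinical)) {
    stage("clinical Spearman correlations")
    clin_cor <- correlate_with_clinical(metrics, config$clinical,
                                        alpha = config$alpha)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model_maps(fit$model, file.path(out_dir, "global_maps.tsv"))
    utils::write.csv(metacriterion_table(fit$report),
                     file.path(out_dir, "metacriterion.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    for (i in seq_along(segs))
      write_segmentation(segs[[i]],
                         file.path(out_dir, sprintf("segmentation_%s.tsv",
                                                    names(segs)[i])))
    if (!is.null(group_tests))
      utils::write.csv(group_tests, file.path(out_dir, "group_tests.csv"),
                       row.names = FALSE)
    if (!is.null(clin_cor))
      utils::write.csv(clin_cor, file.path(out_dir, "clinical_correlations.csv"),
                       row.names = FALSE)
    cfg <- unclass(config)
    cfg$simulation <- unclass(cfg$simulation)
    cfg$clinical <- NULL                     # tabular; written separately
    jsonlite::write_json(cfg, file.path(out_dir, "config_resolved.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(config$clinical))
      utils::write.csv(config$clinical, file.path(out_dir, "clinical.csv"),
                       row.names = FALSE)
    stage(sprintf("outputs written to %s", out_dir))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  structure(
    list(fit = fit, segmentations = segs, metrics = metrics,
         group_tests = group_tests, clinical_correlations = clin_cor,
         truth = truth, config = config),
    class = "pipeline_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, K* = %d, mean subject GEV = %.3f\n",
              length(x$segmentations), x$fit$model$K,
              mean(x$metrics$gev_total)))
  invisible(x)
}
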