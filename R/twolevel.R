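#' Extract the topographies at GFP peaks of a recording
#'
#' @param rec An average-referenced [eeg_recording()].
#' @param min_distance_samples Passed to [find_gfp_peaks()].
#' @return `channels x n_peaks` matrix of peak maps.
#' @export
peak_maps <- function(rec, min_distance_samples = 1) {
  gfp <- compute_gfp(rec)
  pk <- find_gfp_peaks(gfp, min_distance_samples = min_distance_samples)
  rec$data[, pk, drop = FALSE]
}

#' Two-level (individual, then group) microstate clustering
#'
#' Stage one fits each subject's GFP-peak maps with a fixed per-subject class
#' count (`individual_k`, default 6). Stage two pools every subject's
#' prototype maps and clusters them at the group level, choosing the group K
#' with the seven-criterion meta-criterion ([select_optimal_k()]). With a
#' single subject the group model is the clustering of that subject's
#' prototypes.
#'
#' Per-subject seeds are derived from the subject identifier (not the list
#' position), so permuting the subject order changes nothing but the pooling
#' order.
#'
#' @param recordings List of average-referenced [eeg_recording()]s.
#' @param k_range Candidate group-level class counts.
#' @param individual_k Classes fitted per subject at stage one.
#' @param n_restarts,max_iter,tol Clustering settings for both levels.
#' @param seed Base seed.
#' @param min_distance_samples GFP-peak thinning (default 1, none).
#' @return A list of class `two_level_fit`: `model` (the group
#'   `microstate_model`), `report` (the group `metacriterion_report`),
#'   `subject_models`, and `pooled_maps`.
#' @export
two_level_cluster <- function(recordings, k_range = 2:8, individual_k = 6,
                              n_restarts = 20, max_iter = 1000, tol = 1e-6,
                              seed = 1, min_distance_samples = 1) {
  stopifnot(length(recordings) >= 1)
  subject_models <- vector("list", length(recordings))
  names(subject_models) <- vapply(seq_along(recordings), function(i) {
    s <- recordings[[i]]$subject
    if (is.null(s)) sprintf("subject%02d", i) else as.character(s)
  }, character(1))
  for (i in seq_along(recordings)) {
    id <- names(subject_models)[i]
    res <- tryCatch({
      pm <- peak_maps(recordings[[i]], min_distance_samples)
      modified_kmeans(pm, K = individual_k, n_restarts = n_restarts,
                      max_iter = max_iter, tol = tol,
                      seed = derive_seed(seed, sum(utf8ToInt(id))))
    }, error = function(e)
      stop("individual-level clustering failed for subject '", id, "': ",
           conditionMessage(e), call. = FALSE))
    subject_models[[i]] <- res
  }
  pooled <- do.call(cbind, lapply(subject_models, function(m) m$maps))
  k_range <- k_range[k_range <= ncol(pooled)]
  if (!length(k_range)) stop("`k_range` is empty after capping at the pooled map count")
  report <- select_optimal_k(pooled, k_range, n_restarts = n_restarts,
                             max_iter = max_iter, tol = tol,
                             seed = derive_seed(seed, 999))
  structure(
    list(model = report$models[[as.character(report$k_selected)]],
         report = report, subject_models = subject_models,
         pooled_maps = pooled),
    class = "two_level_fit"
  )
}

#' @export
print.two_level_fit <- function(x, ...) {
  cat(sprintf("<two_level_fit> %d subjects -> %d pooled prototype maps\n",
              length(x$subject_models), ncol(x$pooled_maps)))
  print(x$model)
  invisible(x)
}
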