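# Core per-class temporal metrics from a bare label sequence. Edge segments
# (truncated by the start or end of the recording) are excluded from the
# duration mean but counted in coverage and occurrence; a class absent from
# the sequence gets duration NA (not 0) and occurrence/coverage 0.
label_metrics <- function(labels, fs, K, exclude_edge_durations = TRUE) {
  n <- length(labels)
  r <- rle(as.integer(labels))
  m <- length(r$values)
  is_edge <- seq_len(m) %in% c(1L, m)
  out <- data.frame(class = LETTERS[seq_len(K)],
                    duration_ms = NA_real_, occurrence_per_s = 0,
                    coverage = 0, stringsAsFactors = FALSE)
  total_s <- n / fs
  for (k in seq_len(K)) {
    sel <- r$values == k
    if (!any(sel)) next
    lens <- r$lengths[sel]
    dur_lens <- if (exclude_edge_durations) r$lengths[sel & !is_edge] else lens
    if (!length(dur_lens)) dur_lens <- lens      # recording-spanning class: keep its one segment
    out$duration_ms[k] <- mean(dur_lens) / fs * 1000
    out$occurrence_per_s[k] <- sum(sel) / total_s
    out$coverage[k] <- sum(lens) / n
  }
  out
}

#' Temporal metrics of a microstate segmentation
#'
#' Per class: duration (mean uninterrupted dwell in ms), occurrence (segments
#' per second of labeled time) and coverage (fraction of labeled samples).
#' Segments truncated by the recording edges are excluded from the duration
#' mean (truncation biases dwell estimates downward) but contribute to
#' occurrence and coverage, so coverage equals occurrence x duration/1000
#' only up to that edge tolerance. Absent classes get duration `NA` (not 0)
#' and zero occurrence and coverage.
#'
#' @param seg A `segmentation` from [backfit()] / [smooth_labels()].
#' @param subject,group Optional identifiers copied into the result.
#' @param exclude_edge_durations Exclude edge-truncated segments from the
#'   duration mean (default TRUE).
#' @return A data.frame with one row per class: `class`, `duration_ms`,
#'   `occurrence_per_s`, `coverage` (plus `subject`/`group` if given).
#' @export
compute_metrics <- function(seg, subject = NULL, group = NULL,
                            exclude_edge_durations = TRUE) {
  stopifnot(inherits(seg, "segmentation"))
  if (!length(seg$labels)) stop("empty segmentation")
  out <- label_metrics(seg$labels, seg$fs, seg$K, exclude_edge_durations)
  if (!is.null(group)) out <- cbind(group = group, out)
  if (!is.null(subject)) out <- cbind(subject = subject, out)
  out
}

#' Global explained variance of a fitted segmentation
#'
#' Per sample, the variance explained by the assigned class is the squared
#' spatial correlation between the instantaneous topography and the class
#' map, weighted by the squared GFP; each class's GEV is its summed weighted
#' contribution divided by the total squared GFP, and the total GEV is the
#' sum over classes.
#'
#' @param rec The average-referenced [eeg_recording()].
#' @param model The fitted `microstate_model`.
#' @param seg The `segmentation` assigning every sample.
#' @return A list with `gev_per_class` (named by class) and `gev_total`.
#' @export
compute_gev <- function(rec, model, seg) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(seg, "segmentation"))
  if (n_samples(rec) != length(seg$labels))
    stop("recording and segmentation lengths differ")
  corr <- sample_correlations(rec, model)
  gfp2 <- compute_gfp(rec)$values^2
  tot <- sum(gfp2)
  if (tot <= 0) stop("zero total GFP: GEV undefined")
  w <- corr^2 * gfp2                             # n x K weighted explained variance
  per <- vapply(seq_len(model$K), function(k) {
    idx <- seg$labels == k
    if (!any(idx)) 0 else sum(w[idx, k])
  }, numeric(1)) / tot
  names(per) <- colnames(model$maps)
  list(gev_per_class = per, gev_total = sum(per))
}

#' Backfit, smooth and summarize one subject
#'
#' Convenience wrapper chaining [backfit()], [smooth_labels()],
#' [compute_metrics()] and [compute_gev()] for a single recording.
#'
#' @param rec An average-referenced [eeg_recording()].
#' @param model The group `microstate_model`.
#' @param window_half_size,besag_factor Smoothing parameters (defaults 3
#'   and 10).
#' @return A list with `segmentation`, `metrics` (with per-class GEV column
#'   appended) and `gev`.
#' @export
segment_subject <- function(rec, model, window_half_size = 3, besag_factor = 10) {
  gfp <- compute_gfp(rec)
  seg <- backfit(rec, model)
  seg <- smooth_labels(seg, gfp, model, window_half_size = window_half_size,
                       besag_factor = besag_factor)
  met <- compute_metrics(seg, subject = rec$subject, group = rec$group)
  gev <- compute_gev(rec, model, seg)
  met$gev <- gev$gev_per_class
  list(segmentation = seg, metrics = met, gev = gev)
}
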