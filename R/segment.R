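#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels. Callers needing polarity invariance
#' take the absolute value.
#'
#' @param map1,map2 Numeric vectors over the same channel set.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(map1, map2) {
  if (length(map1) != length(map2))
    stop("maps have different channel counts (", length(map1), " vs ",
         length(map2), ")")
  if (stats::sd(map1) == 0 || stats::sd(map2) == 0)
    stop("spatial correlation undefined: zero-variance map")
  stats::cor(map1, map2)
}

# Signed per-sample correlations of a recording with every model map.
# For average-referenced data and unit-norm average-referenced maps this is
# (m . x)/||x||, computed as one matrix product.
sample_correlations <- function(rec, model) {
  if (!identical(rownames(rec$data), rownames(model$maps))) {
    if (!setequal(rec$channel_labels, rownames(model$maps)))
      stop("channel mismatch between recording and model: ",
           paste(union(setdiff(rec$channel_labels, rownames(model$maps)),
                       setdiff(rownames(model$maps), rec$channel_labels)),
                 collapse = ", "))
    model$maps <- model$maps[rec$channel_labels, , drop = FALSE]
  }
  stopifnot_avg_ref(rec$data, tol = 1e-6 * max(1, max(abs(rec$data))))
  A <- crossprod(rec$data, model$maps)          # n x K
  nx <- sqrt(colSums(rec$data^2))
  zero <- which(nx == 0)
  if (length(zero))
    stop("spatial correlation undefined: zero-variance sample(s) at index ",
         paste(utils::head(zero, 5), collapse = ", "))
  A / nx
}

make_segmentation <- function(labels, fs, K, corr) {
  labels <- as.integer(labels)
  r <- rle(labels)
  segs <- data.frame(class = r$values,
                     start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
                     length = r$lengths)
  structure(
    list(labels = labels, fs = fs, K = as.integer(K),
         segments = segs, corr = corr,
         corr_trace = abs(corr[cbind(seq_along(labels), labels)])),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d samples @ %g Hz, K = %d, %d segments\n",
              length(x$labels), x$fs, x$K, nrow(x$segments)))
  invisible(x)
}

#' Backfit a microstate model to every sample of a recording
#'
#' Assigns every sample (not only GFP peaks) to the class whose map has the
#' highest absolute spatial correlation with the instantaneous topography,
#' ignoring polarity; ties go to the lowest class index.
#'
#' @param rec An average-referenced [eeg_recording()].
#' @param model A [modified_kmeans()] model with matching channels.
#' @return A `segmentation`: per-sample `labels` (1..K), derived `segments`,
#'   the signed per-sample/per-class correlation matrix `corr`, and the
#'   winning-correlation trace.
#' @export
backfit <- function(rec, model) {
  corr <- sample_correlations(rec, model)
  labels <- max.col(abs(corr), ties.method = "first")
  make_segmentation(labels, rec$fs, model$K, corr)
}

#' Besag-factor temporal smoothing of a microstate segmentation
#'
#' The classical windowed nonlinear smoothing of microstate segmentation:
#' each sample is iteratively reassigned to the class minimizing
#' `unexplained variance - lambda * N_bkt`, where the data term is the
#' squared-GFP-weighted unexplained variance
#' `gfp_t^2 (1 - r_tk^2) / (2 e (C - 1))` (with `e` the mean residual noise
#' variance of the unsmoothed assignment, held fixed) and `N_bkt` counts the
#' samples labeled k within `±window_half_size` of t, the sample itself
#' included. Iteration stops when no label changes or at `max_iter`. With
#' `lambda = 0` the labels are unchanged. This keeps noise during low-GFP
#' periods from fragmenting segments of stable topography.
#'
#' @param seg A [backfit()] segmentation (carries the correlation matrix).
#' @param gfp The recording's [compute_gfp()] series.
#' @param model The backfitted model (supplies the channel count).
#' @param window_half_size Window half size b in samples (default 3).
#' @param besag_factor Smoothing strength lambda (default 10).
#' @param max_iter Iteration cap.
#' @return A smoothed `segmentation`.
#' @export
smooth_labels <- function(seg, gfp, model, window_half_size = 3,
                          besag_factor = 10, max_iter = 1000) {
  stopifnot(inherits(seg, "segmentation"))
  b <- as.integer(window_half_size)
  lambda <- besag_factor
  if (b < 0) stop("`window_half_size` must be >= 0")
  if (lambda < 0) stop("`besag_factor` must be >= 0")
  if (lambda == 0 || b == 0) return(seg)
  v <- (if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp))^2
  n <- length(seg$labels)
  if (length(v) != n) stop("GFP series and segmentation lengths differ")
  K <- seg$K
  C <- nrow(model$maps)
  # data term: squared-GFP-weighted unexplained variance, noise-normalized
  U <- v * (1 - seg$corr^2)                     # n x K
  e <- sum(U[cbind(seq_len(n), seg$labels)]) / (n * (C - 1))
  if (e <= 0) e <- .Machine$double.eps
  D <- U / (2 * e * (C - 1))
  L <- seg$labels
  # Sites closer than b+1 samples interact through the window count, so
  # samples are updated colour by colour (i mod b+1): sites sharing a colour
  # never neighbour each other, each update minimizes its local objective
  # with the rest fixed, and the relabeling converges instead of entering
  # the 2-cycles a fully synchronous update can fall into.
  colours <- lapply(seq_len(b + 1L), function(c0) seq.int(c0, n, by = b + 1L))
  # The count for class k in [t-b, t+b] includes t itself: a sample lends its
  # own class one vote of support, a hysteresis that protects genuinely brief
  # segments while isolated unsupported blips are still absorbed.
  window_counts <- function(L, k) {
    ind <- as.numeric(L == k)
    cs <- c(0, cumsum(c(rep(0, b), ind, rep(0, b))))
    cs[2L * b + 1L + seq_len(n)] - cs[seq_len(n)]
  }
  for (it in seq_len(max_iter)) {
    changed <- 0L
    for (idx in colours) {
      cost <- D[idx, , drop = FALSE]
      for (k in seq_len(K))
        cost[, k] <- cost[, k] - lambda * window_counts(L, k)[idx]
      Lnew <- max.col(-cost, ties.method = "first")
      changed <- changed + sum(Lnew != L[idx])
      L[idx] <- Lnew
    }
    if (changed == 0L) break
  }
  make_segmentation(L, seg$fs, K, seg$corr)
}
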