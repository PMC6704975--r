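#' Global field power of a recording
#'
#' The GFP at a sample is the population standard deviation (divide by the
#' channel count, not N-1) of the scalp potential across all channels: a
#' reference-free scalar measure of field strength. It is invariant to
#' average referencing and to a global polarity flip.
#'
#' @param rec An [eeg_recording()].
#' @return An object of class `gfp_series`: `values` (per-sample GFP), `fs`,
#'   and the recording's `edge_exclude_s` flag.
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  mu <- colMeans(rec$data)
  v <- colMeans(rec$data^2) - mu^2
  structure(list(values = sqrt(pmax(v, 0)), fs = rec$fs,
                 edge_exclude_s = rec$edge_exclude_s),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples @ %g Hz, mean %.3g, max %.3g\n",
              length(x$values), x$fs, mean(x$values), max(x$values)))
  invisible(x)
}

#' Locate GFP peaks
#'
#' A peak is a strict interior local maximum `values[i-1] < values[i] >
#' values[i+1]`; a plateau (run of equal values higher than both neighbours
#' of the run) contributes its first index. Peaks inside the edge-transient
#' margin are dropped. Optionally the peak set is thinned so surviving peaks
#' are at least `min_distance_samples` apart, keeping the larger (ties: the
#' earlier).
#'
#' @param gfp A `gfp_series` from [compute_gfp()], or a plain numeric vector.
#' @param min_distance_samples Minimum spacing of surviving peaks; 1 (the
#'   default) disables thinning.
#' @param exclude_edges Honour the series' `edge_exclude_s` flag.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(gfp, min_distance_samples = 1, exclude_edges = TRUE) {
  if (inherits(gfp, "gfp_series")) {
    v <- gfp$values
    edge <- if (exclude_edges) round(gfp$edge_exclude_s * gfp$fs) else 0L
  } else {
    v <- as.numeric(gfp); edge <- 0L
  }
  n <- length(v)
  if (n < 3L) return(integer(0))
  # collapse plateaus: compare run values, map back to first index of run
  r <- rle(v)
  m <- length(r$values)
  if (m < 3L) {
    peaks <- integer(0)
  } else {
    rv <- r$values
    is_pk <- c(FALSE, rv[2:(m - 1)] > rv[1:(m - 2)] & rv[2:(m - 1)] > rv[3:m], FALSE)
    starts <- cumsum(c(1L, r$lengths[-m]))
    peaks <- starts[is_pk]
  }
  if (edge > 0L)
    peaks <- peaks[peaks > edge & peaks <= n - edge]
  if (min_distance_samples > 1 && length(peaks) > 1L) {
    ord <- order(-v[peaks], peaks)       # tallest first, ties earlier-first
    kept <- integer(0)
    for (p in peaks[ord]) {
      if (!length(kept) || min(abs(kept - p)) >= min_distance_samples)
        kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  as.integer(peaks)
}
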