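#' Construct an EEG recording
#'
#' The basic container every stage of the pipeline transforms: a
#' channels-by-samples matrix of scalp potentials together with its sampling
#' rate and channel labels, optionally tagged with a subject identifier and a
#' group ("patient" or "control").
#'
#' @param data Numeric matrix, channels in rows, samples in columns (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names; defaults to the
#'   row names of `data` or `"ch001"`, `"ch002"`, ...
#' @param subject Optional subject identifier.
#' @param group Optional group tag, `"patient"` or `"control"`.
#' @param edge_exclude_s Seconds at each end of the recording flagged as
#'   filter edge transients; GFP-peak extraction skips them (see
#'   [bandpass_filter()]).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, subject = NULL,
                          group = NULL, edge_exclude_s = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("an EEG recording needs at least 2 channels, got ", nrow(data))
  if (ncol(data) < 2L)
    stop("an EEG recording needs at least 2 samples, got ", ncol(data))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_labels)) channel_labels <- rownames(data)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%03d", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("length of `channel_labels` (", length(channel_labels),
         ") does not match the number of channels (", nrow(data), ")")
  rownames(data) <- channel_labels
  if (!is.null(group)) group <- match.arg(group, c("patient", "control"))
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject = subject, group = group, edge_exclude_s = edge_exclude_s),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$subject)) cat("  subject:", x$subject,
                               if (!is.null(x$group)) paste0("(", x$group, ")"), "\n")
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec An `eeg_recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's RNG stream. seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small integer stream derived from a base seed, used to hand
# independent sub-seeds to the stages of a simulation or pipeline run.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + 12289 * as.numeric(offset)) %% 2147483L + 1)
}

stopifnot_avg_ref <- function(data, tol = 1e-6, what = "recording") {
  mx <- max(abs(colMeans(data)))
  if (mx > tol)
    stop(what, " must be average-referenced (max per-sample channel mean = ",
         signif(mx, 3), "); call average_reference() first")
  invisible(TRUE)
}
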