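#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`) independently to every channel, so topographies incur
#' no phase distortion. The first and last second of the output are flagged
#' as edge transients (`edge_exclude_s`); downstream GFP-peak extraction
#' skips them.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param edge_s Seconds flagged as edge transient at each end.
#' @return A filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 40, edge_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0)) stop("invalid band edge: `low_hz` (", low_hz, ") must be > 0")
  if (!(high_hz > low_hz))
    stop("invalid band edge: `high_hz` (", high_hz, ") must exceed `low_hz` (", low_hz, ")")
  if (!(high_hz < nyq))
    stop("invalid band edge: `high_hz` (", high_hz, ") must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  dimnames(out$data) <- dimnames(rec$data)
  out$edge_exclude_s <- max(rec$edge_exclude_s, edge_s)
  out
}

# frequency-response magnitude of the zero-phase band-pass at `freq_hz`;
# exported for use as an analytic oracle of the filter's gain
#' Gain of the zero-phase band-pass at a frequency
#'
#' Squared-magnitude response of the Butterworth design used by
#' [bandpass_filter()] (squared because the filter runs forward and
#' backward).
#'
#' @param low_hz,high_hz,fs Filter design parameters.
#' @param freq_hz Frequency at which to evaluate the gain.
#' @return Linear amplitude gain at `freq_hz`.
#' @export
bandpass_gain <- function(low_hz, high_hz, fs, freq_hz) {
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  filter_gain(bf, fs, freq_hz)^2
}

# |H(e^{i w})| of a digital filter at freq_hz, by direct evaluation of the
# transfer-function polynomials on the unit circle
filter_gain <- function(filt, fs, freq_hz) {
  z <- exp(-1i * 2 * pi * freq_hz / fs)
  num <- sum(filt$b * z^(seq_along(filt$b) - 1))
  den <- sum(filt$a * z^(seq_along(filt$a) - 1))
  Mod(num / den)
}

#' Decimate a recording to a lower sampling rate
#'
#' Integer-ratio decimation with a zero-phase anti-aliasing low-pass
#' (8th-order Butterworth at `0.4 * target_fs`) applied first. Non-integer
#' ratios are refused rather than silently resampled. `target_fs == fs` is a
#' no-op.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return A decimated `eeg_recording` with `floor(n * target_fs / fs)`
#'   samples.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("`target_fs` (", target_fs, ") exceeds the sampling rate (", rec$fs, ")")
  r <- rec$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("non-integer decimation ratio ", signif(r, 6),
         " (fs = ", rec$fs, ", target_fs = ", target_fs, "); refusing to resample")
  r <- as.integer(round(r))
  if (r == 1L) return(rec)
  lp <- signal::butter(4, (0.4 * target_fs) / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$data, 1, function(ch) signal::filtfilt(lp, ch)))
  idx <- seq.int(1L, by = r, length.out = ncol(rec$data) %/% r)
  out <- rec
  out$data <- filt[, idx, drop = FALSE]
  dimnames(out$data) <- list(rec$channel_labels, NULL)
  out$fs <- target_fs
  out
}

#' Gain of the anti-aliasing low-pass at a frequency
#'
#' Squared-magnitude response of the decimation low-pass used by
#' [downsample()].
#'
#' @param fs,target_fs Decimation parameters.
#' @param freq_hz Frequency at which to evaluate the gain.
#' @return Linear amplitude gain at `freq_hz`.
#' @export
antialias_gain <- function(fs, target_fs, freq_hz) {
  lp <- signal::butter(4, (0.4 * target_fs) / (fs / 2), type = "low")
  filter_gain(lp, fs, freq_hz)^2
}

#' Re-reference a recording to the average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each sample's channel mean is zero. Idempotent; leaves the GFP unchanged.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Select a subset of channels
#'
#' Models the reduction of a montage to a smaller channel set (e.g. dropping
#' neck and facial electrodes) by an explicit user-provided list.
#'
#' @param rec An [eeg_recording()].
#' @param keep Character vector of channel labels (or integer indices) to keep.
#' @return An `eeg_recording` restricted to `keep`.
#' @export
select_channels <- function(rec, keep) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(keep)) {
    missing <- setdiff(keep, rec$channel_labels)
    if (length(missing))
      stop("unknown channel label(s): ", paste(missing, collapse = ", "))
    keep <- match(keep, rec$channel_labels)
  }
  eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                channel_labels = rec$channel_labels[keep],
                subject = rec$subject, group = rec$group,
                edge_exclude_s = rec$edge_exclude_s)
}
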