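# Minimal continuous EDF reader/writer (16-bit integer samples, fixed-layout
# ASCII header). Covers what this package needs: uniform sampling rate,
# 1-second data records, EDF+ annotation channels skipped on read.

edf_pad <- function(x, width)
  strtrim(formatC(as.character(x), width = width, flag = "-"), width)

#' Write an EEG recording as EDF
#'
#' Continuous EDF with one-second data records; the recording is truncated
#' to a whole number of seconds (with a warning) because EDF stores an
#' integer number of fixed-duration records. Samples are scaled to the
#' 16-bit digital range per channel, so a round trip is exact only up to
#' that quantization.
#'
#' @param rec An [eeg_recording()] whose `fs` is a whole number.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export needs a whole-number sampling rate, got ", fs)
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * fs < ncol(rec$data))
    warning("truncating ", ncol(rec$data) - n_rec * fs,
            " trailing samples to a whole number of EDF records")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  # physical range per channel, serialized to <= 8 bytes and parsed back so
  # the scaling used for writing matches the header the reader will see
  fit8 <- function(x) {
    for (d in c(6, 5, 4, 3, 2, 1)) {
      s <- formatC(x, format = "g", digits = d)
      if (all(nchar(s) <= 8)) return(s)
    }
    formatC(x, format = "e", digits = 0)
  }
  lo <- apply(data, 1, min); hi <- apply(data, 1, max)
  flat <- hi - lo == 0
  hi[flat] <- lo[flat] + 1
  # widen slightly before rounding the header fields so data stays in range
  span <- hi - lo
  phys_min_s <- fit8(lo - 0.001 * span)
  phys_max_s <- fit8(hi + 0.001 * span)
  phys_min <- as.numeric(phys_min_s)
  phys_max <- as.numeric(phys_max_s)
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X X", if (!is.null(rec$subject)) rec$subject else ""), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste(edf_pad(substr(rec$channel_labels, 1, 16), 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),          # transducer
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(phys_min_s, 8), collapse = ""),
    paste(edf_pad(phys_max_s, 8), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),          # prefiltering
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(header, con, eos = NULL)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - phys_min[ch]) * scale[ch]) + dig_min
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses the fixed-layout EDF header and the 16-bit data records, rescales
#' to physical units, and drops annotation channels (`EDF Annotations`) from
#' the data matrix (logged via `message()`). Channels must share one
#' sampling rate.
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < width)
      stop("malformed EDF header in ", path, ": truncated file")
    trimws(raw)
  }
  version <- rd(8)
  if (version != "0") stop("malformed EDF header in ", path,
                           ": unsupported version '", version, "'")
  rd(80); recording_id <- rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header in ", path,
                                 ": bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                         # transducer
  for (i in seq_len(ns)) rd(8)                          # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)                         # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) ||
      is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF header in ", path, ": non-numeric signal fields")
  if (header_bytes != 256L * (1L + ns))
    stop("malformed EDF header in ", path, ": header size field inconsistent")

  is_annot <- grepl("^EDF Annotations", labels)
  keep <- which(!is_annot)
  if (any(is_annot))
    message("read_edf: excluding ", sum(is_annot), " annotation channel(s): ",
            paste(labels[is_annot], collapse = ", "))
  if (length(keep) < 2L)
    stop(path, ": fewer than 2 EEG channels after excluding annotations")
  if (length(unique(spr[keep])) != 1L)
    stop(path, ": mixed per-channel sampling rates are not supported")
  fs <- spr[keep[1]] / rec_dur

  out <- matrix(0, nrow = length(keep), ncol = n_rec * spr[keep[1]])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[ch])
        stop("malformed EDF data in ", path, ": truncated record ", r)
      j <- match(ch, keep)
      if (!is.na(j))
        out[j, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
          (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  subject <- {
    m <- regmatches(recording_id, regexpr("\\S+$", recording_id))
    if (length(m) && !m %in% c("X", "")) m else NULL
  }
  eeg_recording(out, fs, channel_labels = labels[keep], subject = subject)
}
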