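#' Read an EEG recording from file
#'
#' Two formats are supported and yield the identical [eeg_recording()]
#' contract:
#' * `"matrix"`: a delimited text file; lines starting with `#` form a
#'   key-value header (`#fs <Hz>` required; `#subject`, `#group` optional),
#'   then one tab-separated row per channel: label followed by the samples.
#' * `"edf"`: European Data Format (continuous, 16-bit); annotation channels
#'   (`EDF Annotations`) are excluded from the data matrix and logged.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"matrix"` or `"edf"`.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "matrix", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") read_edf(path) else read_eeg_matrix(path)
}

read_eeg_matrix <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx)))
    stop("malformed matrix file ", path, ": header lines (#) must come first")
  hdr <- sub("^#\\s*", "", lines[hdr_idx])
  kv <- strsplit(hdr, "[\t ]+")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  if (!"fs" %in% keys)
    stop("malformed matrix file ", path, ": missing '#fs <Hz>' header line")
  fs <- suppressWarnings(as.numeric(vals[match("fs", keys)]))
  if (is.na(fs) || fs <= 0)
    stop("malformed matrix file ", path, ": fs must be a positive number, got '",
         vals[match("fs", keys)], "'")
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("malformed matrix file ", path, ": no channel rows")
  rows <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("malformed matrix file ", path, ": inconsistent channel lengths (rows ",
         paste(which(lens != lens[1]), collapse = ", "), ")")
  labels <- vapply(rows, `[`, character(1), 1)
  data <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) stop("malformed matrix file ", path,
                       ": non-numeric sample value in channel '", r[1], "'")
    v
  }, numeric(lens[1] - 1L)))
  sub <- if ("subject" %in% keys) vals[match("subject", keys)] else NULL
  grp <- if ("group" %in% keys) vals[match("group", keys)] else NULL
  eeg_recording(data, fs, channel_labels = labels, subject = sub, group = grp)
}

#' Write an EEG recording to file
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"matrix"` or `"edf"`.
#' @param digits Significant digits for the matrix format.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "matrix", "edf"),
                      digits = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") return(write_edf(rec, path))
  hdr <- c(paste0("#fs\t", format(rec$fs, digits = 12)),
           if (!is.null(rec$subject)) paste0("#subject\t", rec$subject),
           if (!is.null(rec$group)) paste0("#group\t", rec$group))
  body <- vapply(seq_len(nrow(rec$data)), function(i) {
    paste(c(rec$channel_labels[i],
            formatC(rec$data[i, ], format = "g", digits = digits)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read ground-truth sidecar files for a synthetic recording
#'
#' The label sequence goes to `<stem>_labels.txt` (one 0-based integer per
#' line) and the per-class true metrics to `<stem>_truth.csv`.
#'
#' @param truth The `truth` element of [synthesize_eeg()].
#' @param stem Path stem for the two sidecar files.
#' @return The two paths, invisibly.
#' @export
write_ground_truth <- function(truth, stem) {
  lab_path <- paste0(stem, "_labels.txt")
  met_path <- paste0(stem, "_truth.csv")
  writeLines(as.character(truth$labels - 1L), lab_path)
  utils::write.csv(truth$metrics, met_path, row.names = FALSE)
  invisible(c(lab_path, met_path))
}

#' Write microstate model maps as a delimited table
#'
#' Channels x K tab-separated table with a header of class labels and a
#' leading channel column.
#'
#' @param model A `microstate_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_maps <- function(model, path) {
  df <- data.frame(channel = rownames(model$maps), model$maps,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a segmentation as a two-column table
#'
#' Tab-separated `sample` (0-based index) and `class` (0-based label).
#'
#' @param seg A `segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  utils::write.table(
    data.frame(sample = seq_along(seg$labels) - 1L, class = seg$labels - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
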