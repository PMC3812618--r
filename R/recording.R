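# Multichannel recording container and its CSV/JSON dialect.

#' Multichannel EEG-like recording
#'
#' A fixed-rate multichannel signal matrix with 10-20-system channel labels
#' and optional cue markers. Samples are stored in rows (one column per
#' channel), the natural layout for R and for the CSV dialect written by
#' [write_recording()]. All sample indices in this package are 1-based.
#'
#' @param data numeric matrix or data frame, samples x channels.
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels; defaults to
#'   `colnames(data)`.
#' @param markers optional data frame with columns `sample` (1-based index)
#'   and `label`.
#' @return an object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(512), 256, 2), 128, c("AF3", "AF4"))
#' rec
#' @export
eeg_recording <- function(data, rate, channels = colnames(data),
                          markers = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) {
    channels <- paste0("CH", seq_len(ncol(data)))
  }
  stopifnot(rate > 0, length(channels) == ncol(data), !anyDuplicated(channels))
  stop_if_not_finite(data, "recording data")
  colnames(data) <- channels
  if (!is.null(markers)) {
    stopifnot(is.data.frame(markers), all(c("sample", "label") %in% names(markers)))
    stopifnot(all(markers$sample >= 1), all(markers$sample <= nrow(data)))
  }
  structure(
    list(data = data, rate = rate, channels = channels, markers = markers),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), nrow(x$data), x$rate, nrow(x$data) / x$rate))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: %d\n", nrow(x$markers)))
  }
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Extract one channel of a recording
#'
#' @param rec an [eeg_recording()].
#' @param channel channel label.
#' @return numeric vector of samples.
#' @export
channel_samples <- function(rec, channel) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!channel %in% rec$channels) {
    stop(sprintf("channel %s not present", channel), call. = FALSE)
  }
  rec$data[, channel]
}

#' Read / write a recording as CSV plus JSON sidecar
#'
#' The on-disk dialect is a headered CSV (rows = samples, columns = channels,
#' header = 10-20 labels) next to a JSON sidecar `<path>.json` holding
#' `rate_hz` and `markers` (1-based sample indices). Values are written with
#' 17 significant digits so the round trip is lossless for doubles.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(apply(rec$data, 2, function(v) sprintf("%.17g", v)))
  names(df) <- rec$channels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(rate_hz = rec$rate)
  if (!is.null(rec$markers)) {
    side$markers <- rec$markers[, c("sample", "label")]
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  markers <- NULL
  if (!is.null(side$markers) && length(side$markers)) {
    markers <- as.data.frame(side$markers)
  }
  eeg_recording(as.matrix(df), rate = as.numeric(side$rate_hz),
                channels = names(df), markers = markers)
}
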