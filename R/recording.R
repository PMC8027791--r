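#' Continuous EEG recording container
#'
#' A lightweight container for a continuous multi-channel recording:
#' a channels x samples matrix in microvolts, the sampling rate, ordered
#' channel labels, and an event table. Event onsets are 0-based sample
#' indices into `[0, n_samples)`; all intervals in the package are
#' half-open `[start, end)`.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate, Hz (> 0).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param events Data frame with columns `onset_sample` (0-based),
#'   `duration` (samples), `code` (character), or NULL.
#' @param meta Optional list of free-form metadata.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, events = NULL, meta = list()) {
  data <- as.matrix(data)
  if (length(channel_labels) == 0) stop("channel list must not be empty")
  if (nrow(data) != length(channel_labels)) {
    stop("data has ", nrow(data), " rows but ", length(channel_labels), " labels")
  }
  if (fs <= 0) stop("fs must be positive")
  n <- ncol(data)
  if (!is.null(events)) {
    events <- as.data.frame(events)
    need <- c("onset_sample", "duration", "code")
    if (!all(need %in% names(events))) {
      stop("events must have columns onset_sample, duration, code")
    }
    if (nrow(events) && (any(events$onset_sample < 0) || any(events$onset_sample >= n))) {
      stop("event onset_sample out of range [0, ", n, ")")
    }
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 events = events, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param x An `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) ncol(x$data)

#' Extract resting segments from a recording
#'
#' Returns the samples covered by `EC` / `EO` events as a list of
#' channels x samples matrices, grouped by condition.
#'
#' @param recording An `eeg_recording` with `EC`/`EO` events.
#' @return Named list with elements `EC` and `EO`, each a list of matrices.
#' @export
resting_segments <- function(recording) {
  ev <- recording$events
  ev <- ev[ev$code %in% c("EC", "EO"), , drop = FALSE]
  if (nrow(ev) == 0) stop("recording has no resting (EC/EO) events")
  out <- list(EC = list(), EO = list())
  for (i in seq_len(nrow(ev))) {
    i0 <- ev$onset_sample[i] + 1L
    i1 <- min(ncol(recording$data), ev$onset_sample[i] + ev$duration[i])
    out[[ev$code[i]]] <- c(out[[ev$code[i]]],
                           list(recording$data[, i0:i1, drop = FALSE]))
  }
  out
}
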