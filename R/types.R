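#' Multichannel EEG recording
#'
#' Container for a multichannel EEG recording sampled at a single fixed rate.
#' Samples are held as a numeric matrix with one column per channel; column
#' names are the channel labels (typically the six 10-20 scalp channels
#' F3, F4, C3, C4, O1, O2 referenced to the mastoids).
#'
#' @param samples Numeric matrix (samples x channels) with unique column
#'   names, or a named list of equal-length numeric vectors.
#' @param sampling_rate Sampling rate in Hz (nominal 200).
#' @param start_time Absolute start time of the recording (`POSIXct`).
#' @return An object of class `eeg_recording` with elements `samples`,
#'   `sampling_rate`, `start_time`.
#' @export
eeg_recording <- function(samples, sampling_rate,
                          start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  if (is.list(samples) && !is.data.frame(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) > 1L)
      stop("all channels must have the same length (got lengths ",
           paste(lens, collapse = ", "), ")")
    samples <- do.call(cbind, lapply(samples, as.numeric))
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  labels <- colnames(samples)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("channel labels are required (matrix column names)")
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", ncol(x$samples), " channel(s) [",
      paste(colnames(x$samples), collapse = ", "), "], ",
      nrow(x$samples), " samples @ ", x$sampling_rate, " Hz, start ",
      format(x$start_time, "%Y-%m-%dT%H:%M:%OS3"), "\n", sep = "")
  invisible(x)
}

#' Channel labels of an EEG recording
#' @param rec An `eeg_recording`.
#' @return Character vector of channel labels.
#' @export
channel_labels <- function(rec) colnames(rec$samples)

#' Eye-aspect-ratio trace
#'
#' Per-video-frame eye-aspect-ratio (EAR) samples at a fixed frame rate.
#' EAR is dimensionless and non-negative; it sits near 0.2-0.4 for an open
#' eye and drops towards 0 during blinks and closures.
#'
#' @param values Numeric vector of per-frame EAR values (finite, >= 0).
#' @param frame_rate Frames per second (nominal 30).
#' @param start_time Absolute time of the first frame (`POSIXct`).
#' @return An object of class `ear_trace`.
#' @export
ear_trace <- function(values, frame_rate = 30,
                      start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("EAR values must be finite")
  if (any(values < 0))
    stop("EAR values must be non-negative")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  structure(
    list(values = values, frame_rate = as.numeric(frame_rate),
         start_time = as.POSIXct(start_time, tz = "UTC")),
    class = "ear_trace"
  )
}

#' @export
print.ear_trace <- function(x, ...) {
  cat("<ear_trace> ", length(x$values), " frames @ ", x$frame_rate,
      " fps (", round(length(x$values) / x$frame_rate, 1), " s)\n", sep = "")
  invisible(x)
}

#' Episode table
#'
#' Ordered, contiguous, alternating wakefulness/drowsiness episodes.
#' Times are seconds from the session start; the absolute session start is
#' kept in the `start_time` attribute so tables can be written with absolute
#' timestamps.
#'
#' @param label Character vector, each `"wake"` or `"drowsy"`.
#' @param start,end Numeric vectors of episode onsets/offsets in seconds
#'   from session start; `end > start` for every episode.
#' @param start_time Absolute session start (`POSIXct`).
#' @param check_tiling If `TRUE` (default) require episodes to be ordered,
#'   non-overlapping and contiguous with strictly alternating labels.
#' @return A `data.frame` of class `episode_table` with columns
#'   `index`, `label`, `start`, `end`.
#' @export
episode_table <- function(label, start, end,
                          start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC"),
                          check_tiling = TRUE) {
  label <- as.character(label)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(label)
  if (length(start) != n || length(end) != n)
    stop("label, start, end must have equal length")
  if (n > 0 && !all(label %in% c("wake", "drowsy")))
    stop("labels must be 'wake' or 'drowsy'")
  if (any(end <= start))
    stop("every episode must satisfy end > start")
  if (n > 1) {
    if (is.unsorted(start, strictly = TRUE))
      stop("episodes must be ordered by start time")
    if (any(start[-1] < end[-n] - 1e-9))
      stop("episodes overlap")
    if (check_tiling) {
      if (any(abs(start[-1] - end[-n]) > 1e-6))
        stop("episodes must tile the session contiguously")
      if (any(label[-1] == label[-n]))
        stop("episode labels must strictly alternate")
    }
  }
  out <- data.frame(index = seq_len(n), label = label,
                    start = start, end = end, stringsAsFactors = FALSE)
  attr(out, "start_time") <- as.POSIXct(start_time, tz = "UTC")
  class(out) <- c("episode_table", "data.frame")
  out
}
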