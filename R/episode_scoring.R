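# PERCLOS / CLOSDUR scoring and segmentation of a session into alternating
# wakefulness/drowsiness episodes.

#' Per-frame eye-state series
#'
#' Holds the per-frame closed/open labels plus the derived closure-duration
#' track. PERCLOS over a window is computed on demand by the scoring
#' functions.
#'
#' @param closed Logical vector, `TRUE` where the eye is closed.
#' @param frame_rate Frames per second.
#' @return An object of class `eye_state_series` with elements `closed`,
#'   `frame_rate`, `closdur` (seconds of ongoing closure per frame).
#' @export
eye_state_series <- function(closed, frame_rate) {
  closed <- as.logical(closed)
  if (anyNA(closed)) stop("closed must not contain NA")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(closed = closed, frame_rate = frame_rate,
                 closdur = closdur_track(closed, frame_rate)),
            class = "eye_state_series")
}

#' @export
print.eye_state_series <- function(x, ...) {
  cat("<eye_state_series> ", length(x$closed), " frames @ ", x$frame_rate,
      " fps, ", round(100 * mean(x$closed), 1), "% closed\n", sep = "")
  invisible(x)
}

#' PERCLOS of a window of frames
#'
#' Fraction of frames with closed eyes among all frames in the window.
#'
#' @param closed Logical vector (non-empty).
#' @return Fraction in \[0, 1\].
#' @export
perclos <- function(closed) {
  if (length(closed) == 0) stop("PERCLOS of an empty window is undefined")
  mean(as.logical(closed))
}

#' Trailing-window PERCLOS track
#'
#' PERCLOS evaluated per frame over a trailing window, truncated at the
#' session start (the first frames use the shorter window actually
#' available).
#'
#' @param closed Logical vector.
#' @param frame_rate Frames per second.
#' @param window Window length in seconds.
#' @return Numeric vector of per-frame PERCLOS values in \[0, 1\].
#' @export
perclos_track <- function(closed, frame_rate, window = 60) {
  n <- length(closed)
  if (n == 0) return(numeric(0))
  w <- max(1L, round(window * frame_rate))
  cs <- cumsum(c(0, as.numeric(closed)))
  i <- seq_len(n)
  a <- pmax(1L, i - w + 1L)
  (cs[i + 1] - cs[a]) / (i - a + 1)
}

#' Ongoing closure duration per frame
#'
#' At each frame, the duration in seconds of the closed run up to and
#' including that frame; 0 on open frames.
#'
#' @param closed Logical vector.
#' @param frame_rate Frames per second (> 0).
#' @return Numeric vector of seconds, same length as `closed`.
#' @export
closdur_track <- function(closed, frame_rate) {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  closed <- as.logical(closed)
  n <- length(closed)
  if (n == 0) return(numeric(0))
  run <- integer(n)
  acc <- 0L
  for (i in seq_len(n)) {
    acc <- if (closed[i]) acc + 1L else 0L
    run[i] <- acc
  }
  run / frame_rate
}

#' Episode-scoring parameters
#'
#' The drowsiness rule is the established criterion PERCLOS >= 0.3 or
#' closure duration >= 2 s; wakefulness is both below. PERCLOS is
#' evaluated over a trailing 60 s window (the NHTSA "within a minute"
#' definition), truncated at session start.
#'
#' @param perclos_window PERCLOS evaluation window, seconds (default 60).
#' @param perclos_threshold Drowsiness PERCLOS cut-off (default 0.3).
#' @param closdur_threshold Drowsiness closure-duration cut-off, seconds
#'   (default 2).
#' @param min_episode Minimum episode duration in seconds; shorter runs are
#'   merged into the previous episode (default 0 = off).
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(perclos_window = 60, perclos_threshold = 0.3,
                           closdur_threshold = 2, min_episode = 0) {
  if (perclos_window <= 0) stop("perclos_window must be > 0")
  if (perclos_threshold <= 0) stop("perclos_threshold must be > 0")
  if (closdur_threshold <= 0) stop("closdur_threshold must be > 0")
  if (min_episode < 0) stop("min_episode must be >= 0")
  structure(list(perclos_window = perclos_window,
                 perclos_threshold = perclos_threshold,
                 closdur_threshold = closdur_threshold,
                 min_episode = min_episode),
            class = "scoring_params")
}

#' Segment a session into alternating wake/drowsy episodes
#'
#' A frame is flagged drowsy when the trailing-window PERCLOS reaches the
#' PERCLOS threshold, or when it belongs to a closure run that eventually
#' reaches the closure-duration threshold (the whole run is flagged
#' retroactively from its first frame, so one closure is never split
#' across two episodes). Maximal same-flag runs become episodes; the
#' resulting table tiles the session contiguously with strictly
#' alternating labels.
#'
#' @param state An `eye_state_series` (from [detect_blinks()] or
#'   [eye_state_series()]).
#' @param params A [scoring_params].
#' @param start_time Absolute session start attached to the table.
#' @return An [episode_table].
#' @export
segment_episodes <- function(state, params = scoring_params(),
                             start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(state, "eye_state_series"))
  closed <- state$closed
  fr <- state$frame_rate
  n <- length(closed)
  if (n == 0) stop("cannot segment an empty state series")

  drowsy <- perclos_track(closed, fr, params$perclos_window) >=
    params$perclos_threshold

  # Retroactive closure rule: flag complete runs reaching the threshold.
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  long <- r$values & (r$lengths / fr >= params$closdur_threshold)
  for (k in which(long)) drowsy[starts[k]:ends[k]] <- TRUE

  runs <- rle(drowsy)
  lab <- ifelse(runs$values, "drowsy", "wake")
  len <- runs$lengths

  # Merge sub-minimum runs into the previous episode (first run never merges
  # backwards; it absorbs forwards instead).
  if (params$min_episode > 0) {
    min_frames <- params$min_episode * fr
    repeat {
      if (length(len) <= 1) break
      short <- which(len < min_frames)
      short <- short[short > 1]
      if (!length(short)) break
      k <- short[1]
      len[k - 1] <- len[k - 1] + len[k]
      len <- len[-k]; lab <- lab[-k]
      # Re-merge neighbours that now carry the same label.
      j <- 1
      while (j < length(lab)) {
        if (lab[j] == lab[j + 1]) {
          len[j] <- len[j] + len[j + 1]
          len <- len[-(j + 1)]; lab <- lab[-(j + 1)]
        } else j <- j + 1
      }
    }
  }

  bounds <- c(0, cumsum(len)) / fr
  episode_table(lab, head(bounds, -1), tail(bounds, -1),
                start_time = start_time)
}

#' Total drowsy time of an episode table
#'
#' @param episodes An [episode_table].
#' @return Seconds labelled drowsy.
#' @export
drowsy_time <- function(episodes) {
  d <- episodes$label == "drowsy"
  sum(episodes$end[d] - episodes$start[d])
}
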