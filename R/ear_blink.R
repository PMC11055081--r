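# Eye-aspect-ratio computation and adaptive-threshold blink detection.
#
# The detector tracks a slow baseline of the EAR signal (median filter, then
# moving average), subtracts a fixed offset to form a per-frame threshold,
# and marks a frame "closed" when the RAW EAR falls below that threshold.
# Comparing the raw signal (not the smoothed one) is essential: at 30 fps a
# 17-frame median spans ~0.57 s and would erase ordinary 100-400 ms blinks
# from the smoothed signal, so the smoothed signal can only serve as the
# baseline tracker.

#' Eye aspect ratio from six eye landmarks
#'
#' EAR = (||p2-p6|| + ||p3-p5||) / (2 ||p1-p4||), where p1/p4 are the eye
#' corners and (p2,p6), (p3,p5) the upper/lower lid point pairs. The ratio
#' is invariant to translation, rotation and uniform scaling of the
#' landmark set. If landmarks for both eyes are supplied the two ratios
#' are averaged.
#'
#' @param landmarks A 6x2 numeric matrix (rows p1..p6, columns x,y), or a
#'   list of such matrices (one per eye).
#' @return A single non-negative ratio.
#' @export
compute_ear <- function(landmarks) {
  if (is.list(landmarks) && !is.matrix(landmarks))
    return(mean(vapply(landmarks, compute_ear, 0)))
  p <- as.matrix(landmarks)
  if (!all(dim(p) == c(6, 2)))
    stop("landmarks must be a 6x2 matrix (p1..p6 by x,y)")
  d <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
  width <- d(1, 4)
  if (width <= .Machine$double.eps)
    stop("degenerate eye width: p1 == p4")
  (d(2, 6) + d(3, 5)) / (2 * width)
}

#' Running median with truncated edge windows
#'
#' Centred running median; windows at the sequence edges shrink to the
#' available samples instead of padding, so no data is fabricated at
#' session boundaries.
#'
#' @param values Numeric vector.
#' @param length Odd window length in frames (>= 1).
#' @return Numeric vector, same length as `values`.
#' @export
median_filter <- function(values, length = 17) {
  if (length < 1 || length %% 2 == 0)
    stop("median filter length must be odd and >= 1")
  n <- base::length(values)
  if (n == 0) return(numeric(0))
  half <- (length - 1) / 2
  trunc_med <- function(i)
    median(values[max(1, i - half):min(n, i + half)])
  if (n <= length || half == 0)
    return(vapply(seq_len(n), trunc_med, 0))
  # interior via the C running median; truncated windows at the edges
  out <- as.numeric(stats::runmed(values, length, endrule = "keep"))
  edge <- c(seq_len(half), (n - half + 1):n)
  out[edge] <- vapply(edge, trunc_med, 0)
  out
}

#' Moving average with truncated edge windows
#'
#' Centred arithmetic-mean smoother; edge windows shrink like in
#' [median_filter()].
#'
#' @param values Numeric vector.
#' @param length Window length in frames (>= 1).
#' @return Numeric vector, same length as `values`.
#' @export
moving_average <- function(values, length = 5) {
  if (length < 1) stop("moving average length must be >= 1")
  n <- base::length(values)
  if (n == 0) return(numeric(0))
  lo <- floor((length - 1) / 2)
  hi <- length - 1 - lo
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  a <- pmax(1, i - lo)
  b <- pmin(n, i + hi)
  (cs[b + 1] - cs[a]) / (b - a + 1)
}

#' Blink-detector parameters
#'
#' Defaults follow the adaptive-threshold configuration: median length 17
#' frames, moving-average length 5 frames, offset 0.04 EAR units. A fixed
#' threshold mode (0.2 by default, the conventional fixed EAR cut-off) is
#' provided for comparison; it misses shallow dips on a high baseline that
#' the adaptive mode catches.
#'
#' @param median_length Median filter length, odd frames (default 17).
#' @param ma_length Moving-average length, frames (default 5).
#' @param offset Subtracted constant, EAR units (default 0.04, > 0).
#' @param min_blink_frames Minimum closed-run length kept as a blink
#'   (default 2 frames, ~67 ms at 30 fps, rejecting single-frame noise).
#' @param mode `"adaptive"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold used in fixed mode (default 0.2).
#' @param refine_iterations Iterative baseline refinement passes
#'   (default 100, converging early; 0 disables). Each pass replaces below-threshold frames
#'   with the last open-eye value before recomputing the baseline, so a
#'   sustained closure cannot drag the baseline (and hence the threshold)
#'   down to the closed-eye level. Without refinement, closures longer
#'   than the median window are truncated to their onset and the
#'   2-second closure criterion can never fire.
#' @return A list of class `blink_params`.
#' @export
blink_params <- function(median_length = 17, ma_length = 5, offset = 0.04,
                         min_blink_frames = 2,
                         mode = c("adaptive", "fixed"), fixed_threshold = 0.2,
                         refine_iterations = 100) {
  mode <- match.arg(mode)
  if (median_length < 1 || median_length %% 2 == 0)
    stop("median_length must be odd and >= 1")
  if (ma_length < 1) stop("ma_length must be >= 1")
  if (offset <= 0) stop("offset must be > 0")
  if (min_blink_frames < 1) stop("min_blink_frames must be >= 1")
  if (refine_iterations < 0) stop("refine_iterations must be >= 0")
  structure(list(median_length = median_length, ma_length = ma_length,
                 offset = offset, min_blink_frames = min_blink_frames,
                 mode = mode, fixed_threshold = fixed_threshold,
                 refine_iterations = refine_iterations),
            class = "blink_params")
}

#' Per-frame adaptive threshold for an EAR trace
#'
#' The base threshold is
#' `moving_average(median_filter(EAR)) - offset` per frame. With
#' `refine_iterations > 0` (the default) the threshold is then refined
#' iteratively: frames currently below the threshold are treated as
#' closed-eye samples and replaced by the preceding open-eye value before
#' the baseline filters are re-applied, until the closed set stops
#' changing. This keeps the baseline anchored to the open-eye level
#' through sustained closures. In fixed mode the threshold is constant.
#'
#' @param trace An [ear_trace] (or bare numeric vector of EAR values).
#' @param params A [blink_params].
#' @return Numeric vector of per-frame thresholds, same length as the trace.
#' @export
adaptive_threshold <- function(trace, params = blink_params()) {
  values <- if (inherits(trace, "ear_trace")) trace$values else as.numeric(trace)
  n <- length(values)
  if (n == 0) return(numeric(0))
  if (params$mode == "fixed")
    return(rep(params$fixed_threshold, n))
  baseline <- function(v)
    moving_average(median_filter(v, params$median_length), params$ma_length) -
      params$offset
  thr <- baseline(values)
  # The closed set grows monotonically: once a frame is suspected closed
  # it stays excluded from the baseline, so the baseline walks back out
  # of a sustained closure a half-window per pass until it sits on
  # open-eye data only.
  closed <- values < thr
  for (i in seq_len(params$refine_iterations)) {
    if (!any(closed) || all(closed)) break
    open_idx <- which(!closed)
    src <- findInterval(seq_len(n), open_idx)
    src[src == 0] <- 1                      # leading closure: first open value
    filled <- values[open_idx[src]]
    thr <- baseline(filled)
    grown <- (values < thr) & !closed
    if (!any(grown)) break
    closed <- closed | grown
  }
  thr
}

#' Detect blinks and eye closures in an EAR trace
#'
#' A frame is "closed" iff the raw EAR falls strictly below the per-frame
#' threshold; maximal closed runs of at least `min_blink_frames` frames
#' become blink events. Shorter runs are treated as noise and re-opened in
#' the returned state series.
#'
#' @param trace An [ear_trace].
#' @param params A [blink_params].
#' @return A list with `blinks` (data frame: `start_frame`, `end_frame`
#'   inclusive 1-based indices, `duration` seconds) and `state` (an
#'   `eye_state_series`, see [eye_state_series()]).
#' @export
detect_blinks <- function(trace, params = blink_params()) {
  stopifnot(inherits(trace, "ear_trace"))
  values <- trace$values
  n <- length(values)
  if (params$mode == "adaptive" && n > 0 && n <= params$median_length)
    warning("trace shorter than the median window; baseline poorly defined")
  thr <- adaptive_threshold(trace, params)
  closed_raw <- values < thr
  closed <- logical(n)
  blinks <- data.frame(start_frame = integer(0), end_frame = integer(0),
                       duration = numeric(0))
  if (n > 0 && any(closed_raw)) {
    r <- rle(closed_raw)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= params$min_blink_frames
    if (any(keep)) {
      blinks <- data.frame(
        start_frame = starts[keep],
        end_frame = ends[keep],
        duration = r$lengths[keep] / trace$frame_rate
      )
      for (k in which(keep)) closed[starts[k]:ends[k]] <- TRUE
    }
  }
  list(blinks = blinks,
       state = eye_state_series(closed, trace$frame_rate))
}
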