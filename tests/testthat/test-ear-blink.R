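test_that("EAR follows the two-vertical-over-horizontal landmark ratio", {
  lm <- rbind(p1 = c(0, 3), p2 = c(1, 4), p3 = c(3, 4),
              p4 = c(4, 3), p5 = c(3, 2), p6 = c(1, 2))
  expect_equal(compute_ear(lm), 0.5)           # (2 + 2) / (2 * 4)
  closed <- lm; closed["p6", ] <- closed["p2", ]; closed["p5", ] <- closed["p3", ]
  expect_equal(compute_ear(closed), 0)
  expect_equal(compute_ear(lm * 7), 0.5)       # scale invariance
  th <- 0.7                                    # rotation + translation invariance
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(compute_ear(sweep(lm %*% R, 2, c(11, -4), "+")), 0.5)
  expect_equal(compute_ear(list(lm, lm * 2)), 0.5)  # two-eye mean
  degenerate <- lm; degenerate["p4", ] <- degenerate["p1", ]
  expect_error(compute_ear(degenerate), "degenerate")
})

test_that("median filter matches the brute-force sort-and-middle oracle", {
  set.seed(7)
  x <- runif(25)
  for (len in c(1, 5, 17)) {
    half <- (len - 1) / 2
    oracle <- vapply(seq_along(x), function(i) {
      w <- sort(x[max(1, i - half):min(25, i + half)])
      m <- length(w)
      # truncated edge windows can have even length: average the middles
      if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
    }, 0)
    expect_equal(median_filter(x, len), oracle)
  }
  expect_equal(median_filter(rep(0.3, 40), 17), rep(0.3, 40))
  dip <- rep(0.3, 40); dip[20] <- 0.1
  expect_equal(median_filter(dip, 17), rep(0.3, 40))  # 1 of 17 cannot move the median
  expect_error(median_filter(x, 4), "odd")
  expect_error(median_filter(x, 0), "odd")
})

test_that("moving average matches the brute-force window-mean oracle", {
  set.seed(8)
  x <- rnorm(30)
  for (len in c(1, 2, 5, 9)) {
    lo <- floor((len - 1) / 2); hi <- len - 1 - lo
    oracle <- vapply(seq_along(x), function(i)
      mean(x[max(1, i - lo):min(30, i + hi)]), 0)
    expect_equal(moving_average(x, len), oracle)
  }
  expect_equal(moving_average(rep(0.3, 10), 5), rep(0.3, 10))
  alt <- rep(c(0, 1), 10)
  # forward-leaning even window [i, i+1]: 0.5 until the truncated last frame
  expect_equal(moving_average(alt, 2)[1:19], rep(0.5, 19))
  expect_error(moving_average(x, 0), ">= 1")
})

test_that("adaptive threshold tracks the smoothed baseline minus the offset", {
  expect_equal(adaptive_threshold(ear_trace(rep(0.30, 60), 30)),
               rep(0.26, 60))
  # a brief 7-frame dip cannot move the 17-frame median baseline
  dip <- rep(0.30, 120); dip[50:56] <- 0.05
  thr <- adaptive_threshold(ear_trace(dip, 30))
  expect_true(all(abs(thr[40:70] - 0.26) < 1e-9))
  expect_identical(adaptive_threshold(numeric(0)), numeric(0))
  # without refinement the threshold is the plain filter composition
  set.seed(9)
  x <- pmax(0, 0.3 + 0.02 * rnorm(100))
  expect_equal(adaptive_threshold(ear_trace(x, 30),
                                  blink_params(refine_iterations = 0)),
               moving_average(median_filter(x, 17), 5) - 0.04)
})

test_that("iterative refinement keeps sustained closures below the threshold", {
  # 3 s closure at 30 fps: much longer than the 17-frame median window
  v <- rep(0.30, 600); v[200:289] <- 0.05
  det <- detect_blinks(ear_trace(v, 30))
  expect_equal(nrow(det$blinks), 1)
  expect_equal(det$blinks$start_frame, 200)
  expect_equal(det$blinks$end_frame, 289)
  expect_gte(max(closdur_track(det$state$closed, 30)), 2)
  # without refinement the baseline collapses onto the closure and only
  # its onset is detected
  det0 <- detect_blinks(ear_trace(v, 30), blink_params(refine_iterations = 0))
  expect_lt(sum(det0$state$closed), 30)
})

test_that("blink detection equals the frame-by-frame threshold oracle", {
  v <- rep(0.30, 300); v[100:106] <- 0.10
  det <- detect_blinks(ear_trace(v, 30))
  expect_equal(det$blinks$start_frame, 100)
  expect_equal(det$blinks$end_frame, 106)
  expect_equal(det$blinks$duration, 7 / 30)

  # no dips -> no blinks
  expect_equal(nrow(detect_blinks(ear_trace(rep(0.3, 300), 30))$blinks), 0)

  # two dips separated by an above-threshold frame -> two events
  v2 <- rep(0.30, 300); v2[100:104] <- 0.1; v2[110:115] <- 0.1
  expect_equal(nrow(detect_blinks(ear_trace(v2, 30))$blinks), 2)

  # oracle equivalence on random traces: every maximal run of
  # raw < threshold with length >= min frames is reported exactly
  set.seed(10)
  for (rep_i in 1:20) {
    x <- pmax(0, 0.3 + 0.02 * rnorm(200))
    x[sample(30:170, 1) + 0:4] <- 0.05
    tr <- ear_trace(x, 30)
    det <- detect_blinks(tr)
    thr <- adaptive_threshold(tr)
    below <- x < thr
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= 2
    expect_equal(det$blinks$start_frame, starts[keep])
    expect_equal(det$blinks$end_frame, ends[keep])
  }
})

test_that("blink events are disjoint, ordered and unaffected by a constant shift", {
  set.seed(11)
  x <- pmax(0, 0.3 + 0.03 * rnorm(400))
  x[80:85] <- 0.02; x[200:203] <- 0.02
  det1 <- detect_blinks(ear_trace(x, 30))
  b <- det1$blinks
  expect_true(all(diff(b$start_frame) > 0))
  expect_true(all(b$end_frame - b$start_frame + 1 >= 2))
  if (nrow(b) > 1)
    expect_true(all(b$start_frame[-1] > b$end_frame[-nrow(b)]))
  # adding a constant shifts the adaptive threshold equally
  det2 <- detect_blinks(ear_trace(x + 0.1, 30))
  expect_equal(det2$blinks, det1$blinks)
})

test_that("adaptive mode catches shallow dips on a high baseline that fixed mode misses", {
  v <- rep(0.34, 300)
  v[100:105] <- 0.25   # dip above the 0.2 fixed threshold
  adaptive <- detect_blinks(ear_trace(v, 30))
  fixed <- detect_blinks(ear_trace(v, 30), blink_params(mode = "fixed"))
  expect_equal(nrow(adaptive$blinks), 1)
  expect_equal(nrow(fixed$blinks), 0)
  # deep dips below 0.2 are found by the fixed mode
  v[200:205] <- 0.1
  expect_equal(nrow(detect_blinks(ear_trace(v, 30),
                                  blink_params(mode = "fixed"))$blinks), 1)
})
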