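test_that("PERCLOS is the closed-frame fraction", {
  expect_equal(perclos(c(rep(TRUE, 18), rep(FALSE, 42))), 0.3)
  expect_equal(perclos(rep(FALSE, 10)), 0)
  expect_equal(perclos(rep(TRUE, 10)), 1)
  expect_equal(perclos(c(rep(TRUE, 7), rep(FALSE, 14))), 1 / 3)
  expect_error(perclos(logical(0)), "empty")
})

test_that("closure-duration track matches a run-length scan", {
  expect_equal(closdur_track(rep(TRUE, 60), 30)[60], 2.0)
  expect_equal(closdur_track(rep(FALSE, 50), 30), rep(0, 50))
  closed <- c(FALSE, rep(TRUE, 3), FALSE, rep(TRUE, 5), FALSE)
  got <- closdur_track(closed, 30)
  expect_equal(max(got[2:4]), 3 / 30, tolerance = 1e-9)
  expect_equal(max(got[6:10]), 5 / 30, tolerance = 1e-9)
  # oracle: explicit scan on random masks
  set.seed(12)
  for (i in 1:10) {
    m <- runif(100) < 0.3
    acc <- 0; oracle <- numeric(100)
    for (k in 1:100) { acc <- if (m[k]) acc + 1 else 0; oracle[k] <- acc / 30 }
    expect_equal(closdur_track(m, 30), oracle)
  }
  expect_error(closdur_track(TRUE, 0), "> 0")
})

test_that("an all-open session is one wake episode; one long closure splits it W/D/W", {
  st <- eye_state_series(rep(FALSE, 3000), 30)
  ep <- segment_episodes(st)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$label, "wake")
  expect_equal(c(ep$start, ep$end), c(0, 100))

  closed <- rep(FALSE, 3000); closed[901:990] <- TRUE  # 3 s closure
  ep2 <- segment_episodes(eye_state_series(closed, 30))
  expect_equal(ep2$label, c("wake", "drowsy", "wake"))
  # retroactive rule: drowsiness starts at the closure's first frame
  expect_equal(ep2$start[2], 900 / 30)
  expect_true(ep2$end[2] >= 990 / 30)
})

test_that("episode tables tile the session with alternating labels", {
  set.seed(13)
  for (i in 1:5) {
    closed <- runif(4000) < 0.1
    closed[sample(1000:2500, 1) + 0:80] <- TRUE
    ep <- segment_episodes(eye_state_series(closed, 30))
    expect_equal(ep$start[1], 0)
    expect_equal(ep$end[nrow(ep)], 4000 / 30, tolerance = 1e-9)
    if (nrow(ep) > 1) {
      expect_equal(ep$start[-1], ep$end[-nrow(ep)])
      expect_true(all(ep$label[-1] != ep$label[-nrow(ep)]))
    }
  }
})

test_that("raising either threshold never increases total drowsy time", {
  set.seed(14)
  closed <- runif(6000) < 0.25
  closed[2000:2100] <- TRUE
  st <- eye_state_series(closed, 30)
  base <- drowsy_time(segment_episodes(st))
  for (pt in c(0.35, 0.5, 0.8)) {
    t <- drowsy_time(segment_episodes(st, scoring_params(perclos_threshold = pt)))
    expect_lte(t, base + 1e-9)
  }
  for (ct in c(3, 5)) {
    t <- drowsy_time(segment_episodes(st, scoring_params(closdur_threshold = ct)))
    expect_lte(t, base + 1e-9)
  }
})

test_that("simulated sessions with strong closure statistics are recovered episode-for-episode", {
  sched <- data.frame(label = c("wake", "drowsy", "wake", "drowsy", "wake"),
                      start = c(0, 90, 130, 240, 300),
                      end = c(90, 130, 240, 300, 390))
  ses <- simulate_session(sim_config(seed = 21, duration = 390,
                                     episode_schedule = sched,
                                     drowsy_closure_fraction = 0.85,
                                     drowsy_closure_duration = c(4, 8)))
  det <- detect_blinks(ses$ear)
  # min_episode merges the sub-threshold wake slivers the trailing
  # PERCLOS window leaves between closures early in a drowsy segment
  ep <- segment_episodes(det$state, scoring_params(min_episode = 3))
  expect_equal(sum(ep$label == "drowsy"), 2)
  # >= 95% of true drowsy time is labelled drowsy
  fr <- ses$ear$frame_rate
  n <- length(ses$ear$values)
  t <- (seq_len(n) - 0.5) / fr
  truth_drowsy <- rep(FALSE, n); got_drowsy <- rep(FALSE, n)
  for (k in which(sched$label == "drowsy"))
    truth_drowsy[t >= sched$start[k] & t < sched$end[k]] <- TRUE
  for (k in which(ep$label == "drowsy"))
    got_drowsy[t >= ep$start[k] & t < ep$end[k]] <- TRUE
  recall <- sum(truth_drowsy & got_drowsy) / sum(truth_drowsy)
  expect_gte(recall, 0.95)
})
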