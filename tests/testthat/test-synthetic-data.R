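test_that("the same seed reproduces the session bit for bit", {
  a <- simulate_session(sim_config(seed = 41, duration = 60))
  b <- simulate_session(sim_config(seed = 41, duration = 60))
  expect_identical(a$ear$values, b$ear$values)
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$truth$episodes, b$truth$episodes)
  c <- simulate_session(sim_config(seed = 42, duration = 60))
  expect_false(identical(a$eeg$samples, c$eeg$samples))
})

test_that("generated band powers close the loop with the feature extractor within 15%", {
  sched <- data.frame(label = c("wake", "drowsy"), start = c(0, 60),
                      end = c(60, 120))
  cfg <- sim_config(seed = 43, duration = 120, episode_schedule = sched)
  ses <- simulate_session(cfg)
  fs <- cfg$eeg_rate
  for (ch in c("F4", "C3")) {
    g <- cfg$channel_gain[[ch]]
    wake_seg <- ses$eeg$samples[1:(60 * fs), ch]
    drow_seg <- ses$eeg$samples[(60 * fs + 1):(120 * fs), ch]
    sw <- welch_psd(wake_seg, fs); sd_ <- welch_psd(drow_seg, fs)
    for (b in c("delta", "theta", "alpha")) {
      target_w <- cfg$band_power_wake[[b]]
      target_d <- target_w + g * (cfg$band_power_drowsy[[b]] - target_w)
      expect_equal(band_power_spec(sw, band_edges(b)) / target_w, 1,
                   tolerance = 0.15)
      expect_equal(band_power_spec(sd_, band_edges(b)) / target_d, 1,
                   tolerance = 0.15)
    }
  }
})

test_that("drowsy segments carry the configured closure statistics", {
  sched <- data.frame(label = c("wake", "drowsy", "wake"),
                      start = c(0, 120, 200), end = c(120, 200, 300))
  ses <- simulate_session(sim_config(seed = 44, duration = 300,
                                     episode_schedule = sched))
  det <- detect_blinks(ses$ear)
  closed <- det$state$closed
  fr <- ses$ear$frame_rate
  drowsy_frames <- (120 * fr + 1):(200 * fr)
  wake_frames <- 1:(120 * fr)
  # drowsy PERCLOS near the 0.4 target; wake PERCLOS far below 0.3
  expect_equal(mean(closed[drowsy_frames]), 0.4, tolerance = 0.15)
  expect_lt(mean(closed[wake_frames]), 0.1)
  # at least one closure reaching the 2 s criterion inside the drowsy block
  expect_gte(max(closdur_track(closed[drowsy_frames], fr)), 2)
})

test_that("ground-truth directions follow the configured band targets", {
  cfg <- sim_config(seed = 45, duration = 30)
  dirs <- simulate_session(cfg)$truth$directions
  f4 <- dirs[dirs$channel == "F4", ]
  expect_equal(f4$direction[f4$feature == "theta_alpha"], "increases")
  expect_equal(f4$direction[f4$feature == "psd_alpha"], "decreases")
  expect_equal(f4$direction[f4$feature == "delta_theta"], "increases")
  expect_equal(f4$direction[f4$feature == "spectral_centroid"], "decreases")
  # null configuration: no direction anywhere
  dirs0 <- simulate_session(sim_config(seed = 45, duration = 30,
                                       effect = "null"))$truth$directions
  expect_true(all(dirs0$direction == "none"))
})

test_that("the fixture suite writes deterministic, re-readable files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, seed = 5)
  f2 <- make_fixture_suite(d2, seed = 5)
  expect_true(all(file.exists(f1)))
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1)) {
    expect_identical(readBin(f1[k], "raw", file.size(f1[k])),
                     readBin(f2[k], "raw", file.size(f2[k])),
                     info = basename(f1[k]))
  }
  # round-trip: every file re-reads
  tr <- read_ear_trace(file.path(d1, "ear_one_blink.csv"))
  expect_equal(nrow(detect_blinks(tr)$blinks), 1)
  rec <- read_eeg(file.path(d1, "session3", "eeg.edf"))
  expect_equal(channel_labels(rec), c("F3", "F4", "C3", "C4", "O1", "O2"))
  ep <- read_episode_table(file.path(d1, "session3", "episodes.csv"))
  expect_equal(ep$label, c("wake", "drowsy", "wake"))
})

test_that("the cohort fixtures run through the whole pipeline without error", {
  d <- withr::local_tempdir()
  make_fixture_suite(d, seed = 6)
  fms <- lapply(list.files(file.path(d, "cohort"), full.names = TRUE), function(p) {
    rec <- read_eeg(file.path(p, "eeg.csv"))
    ep <- read_episode_table(file.path(p, "episodes.csv"))
    episode_features(design_apply_fir(rec), ep)
  })
  names(fms) <- paste0("s", seq_along(fms))
  rep <- build_report(fms)
  expect_s3_class(rep, "sensitivity_report")
  expect_true(all(rep$table$mean_pct >= 0 & rep$table$mean_pct <= 100))
})
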