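test_that("channel sensitivity is the concordant fraction in percent", {
  expect_equal(channel_sensitivity(23, total = 29), 79.31034, tolerance = 1e-5)
  lab <- structure(data.frame(episode = 1:4, label = "wake",
                              correlated = c(TRUE, TRUE, FALSE, FALSE)),
                   class = c("episode_labels", "data.frame"))
  expect_equal(channel_sensitivity(lab), 50)
  expect_equal(channel_sensitivity(0, total = 10), 0)
  expect_equal(channel_sensitivity(10, total = 10), 100)
  expect_error(channel_sensitivity(1, total = 0), "positive")
})

test_that("average sensitivity is the arithmetic mean across subjects", {
  expect_equal(average_sensitivity(c(50, 100)), 75)
  expect_equal(average_sensitivity(rep(62.5, 7)), 62.5)
  set.seed(27)
  v <- runif(50, 0, 100)
  expect_equal(average_sensitivity(v), sum(v) / 50)
  expect_error(average_sensitivity(numeric(0)), "empty")
})

test_that("combine sensitivity is the union rule over the channel set", {
  mk <- function(corr) structure(
    data.frame(episode = seq_along(corr), label = "drowsy", correlated = corr),
    class = c("episode_labels", "data.frame"))
  A <- mk(c(TRUE, TRUE, TRUE, FALSE, FALSE))
  B <- mk(c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(combine_sensitivity(list(A = A, B = B)), 80)  # union misses only ep 5
  C1 <- mk(c(TRUE, FALSE, FALSE, FALSE, FALSE))
  C2 <- mk(c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(combine_sensitivity(list(C1, C2)), 100)
  expect_equal(combine_sensitivity(list(A = A)), channel_sensitivity(A))
})

test_that("match percentages reproduce the report-stage arithmetic", {
  m <- match_percentages(427, 453, 451, 474)
  expect_equal(m$drowsy_pct, 94.3)
  expect_equal(m$wake_pct, 95.1)
  expect_equal(m$overall_pct, 94.7)
  expect_equal(sum(m$counts[c("drowsy_total", "wake_total")]), 927)
})

test_that("the cohort report nests union monotonicity: all >= region >= channel", {
  sched <- alt_schedule(20, 8)
  cohort <- simulate_cohort(
    sim_config(seed = 31, duration = 160, episode_schedule = sched), 2)
  fms <- lapply(cohort, function(s)
    episode_features(design_apply_fir(s$eeg), s$truth$episodes))
  rep <- build_report(fms)
  for (feat in c("theta_alpha", "psd_alpha", "spectral_centroid")) {
    tf <- rep$table[rep$table$feature == feat, ]
    all_pct <- tf$mean_pct[tf$scope == "all"]
    for (rg in c("F3/F4", "C3/C4", "O1/O2")) {
      rg_pct <- tf$mean_pct[tf$scope == "region" & tf$scope_members == rg]
      expect_lte(rg_pct, all_pct + 1e-9)
      for (ch in strsplit(rg, "/")[[1]]) {
        ch_pct <- tf$mean_pct[tf$scope == "channel" & tf$scope_members == ch]
        expect_lte(ch_pct, rg_pct + 1e-9)
      }
    }
    expect_true(all(tf$mean_pct >= 0 & tf$mean_pct <= 100))
  }
})

test_that("the report is reproducible and collapses to channel sensitivity for one subject", {
  sched <- alt_schedule(10, 8)
  ses <- simulate_session(sim_config(seed = 32, duration = 80,
                                     episode_schedule = sched))
  fm <- episode_features(design_apply_fir(ses$eeg), ses$truth$episodes)
  r1 <- build_report(list(s1 = fm))
  r2 <- build_report(list(s1 = fm))
  expect_identical(r1$table, r2$table)
  f4 <- r1$table[r1$table$feature == "theta_alpha" &
                   r1$table$scope == "channel" & r1$table$scope_members == "F4", ]
  expect_equal(f4$mean_pct,
               channel_sensitivity(label_episodes(fm, "F4", "theta_alpha")))
})

test_that("the report ranks the channel carrying the largest configured effect first", {
  gains <- c(F3 = 0.2, F4 = 1.0, C3 = 0.1, C4 = 0.1, O1 = 0.15, O2 = 0.3)
  sched <- alt_schedule(40, 8)
  cohort <- simulate_cohort(
    sim_config(seed = 33, duration = 320, episode_schedule = sched,
               channel_gain = gains), 2)
  fms <- lapply(cohort, function(s)
    episode_features(design_apply_fir(s$eeg), s$truth$episodes))
  rep <- build_report(fms)
  expect_equal(rep$best$best_channel[rep$best$feature == "theta_alpha"], "F4")
})
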