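test_that("there are exactly ten criteria with the documented trends", {
  fc <- feature_criteria()
  expect_equal(nrow(fc), 10)
  expect_setequal(fc$feature, feature_names())
  up <- fc$feature[fc$direction == "increases"]
  expect_setequal(up, c("psd_delta", "psd_theta", "theta_alpha",
                        "delta_alpha", "delta_theta", "spectral_spread"))
})

test_that("the drowsy criterion compares against both wake neighbours", {
  fm <- toy_features(c("wake", "drowsy", "wake"), c(0.8, 1.2, 0.9))
  expect_true(evaluate_criterion(fm, 2, "F4", "theta_alpha"))
  fm2 <- toy_features(c("wake", "drowsy", "wake"), c(1.2, 1.0, 0.9))
  expect_false(evaluate_criterion(fm2, 2, "F4", "theta_alpha"))
  fm3 <- toy_features(c("wake", "drowsy", "wake"), c(5.0, 3.0, 4.0),
                      feature = "psd_alpha")
  expect_true(evaluate_criterion(fm3, 2, "F4", "psd_alpha"))
  expect_error(evaluate_criterion(fm, 1, "F4", "theta_alpha"), "not a drowsy")
  # boundary drowsy episode: single available comparison decides
  fmb <- toy_features(c("drowsy", "wake"), c(1.5, 1.0))
  expect_true(evaluate_criterion(fmb, 1, "F4", "theta_alpha"))
})

test_that("episode labelling applies the mirrored rule to wake episodes", {
  fm <- toy_features(c("wake", "drowsy", "wake"), c(0.8, 1.2, 0.9))
  lab <- label_episodes(fm, "F4", "theta_alpha")
  expect_true(all(lab$correlated))

  fm2 <- toy_features(c("wake", "drowsy", "wake"), c(1.2, 1.0, 0.9))
  lab2 <- label_episodes(fm2, "F4", "theta_alpha")
  # oracle (direct rule evaluation): D fails (1.0 < 1.2); wake 1 fails
  # (1.2 > 1.0, not below its drowsy neighbour); wake 3 holds (0.9 < 1.0)
  expect_equal(lab2$correlated, c(FALSE, FALSE, TRUE))
})

test_that("one satisfying channel suffices (union rule) and more channels never hurt", {
  vals <- list(F3 = c(1.2, 1.0, 0.9), F4 = c(0.8, 1.2, 0.9))
  fm <- toy_features(c("wake", "drowsy", "wake"), vals,
                     channels = c("F3", "F4"))
  lab_f3 <- label_episodes(fm, "F3", "theta_alpha")
  lab_both <- label_episodes(fm, c("F3", "F4"), "theta_alpha")
  expect_true(lab_both$correlated[2])
  expect_true(all(lab_both$correlated >= lab_f3$correlated))

  set.seed(24)
  for (i in 1:10) {
    labels <- rep(c("wake", "drowsy"), length.out = 9)
    vals <- list(F3 = runif(9), F4 = runif(9), O2 = runif(9))
    fm <- toy_features(labels, vals, channels = c("F3", "F4", "O2"))
    small <- label_episodes(fm, c("F3", "F4"), "theta_alpha")$correlated
    big <- label_episodes(fm, c("F3", "F4", "O2"), "theta_alpha")$correlated
    expect_true(all(big >= small))
  }
  expect_error(label_episodes(fm, character(0), "theta_alpha"), "non-empty")
})

test_that("criterion outcomes are invariant to strictly increasing transforms", {
  set.seed(25)
  labels <- rep(c("wake", "drowsy"), length.out = 11)
  v <- runif(11)
  for (f in c("theta_alpha", "psd_alpha", "spectral_rolloff")) {
    a <- label_episodes(toy_features(labels, v, feature = f), "F4", f)$correlated
    b <- label_episodes(toy_features(labels, exp(3 * v) + 1, feature = f),
                        "F4", f)$correlated
    expect_identical(a, b)
  }
})

test_that("under an i.i.d. null an interior drowsy episode passes with probability 1/3", {
  set.seed(26)
  n_ep <- 4001
  labels <- rep(c("wake", "drowsy"), length.out = n_ep)
  v <- rnorm(n_ep)
  lab <- label_episodes(toy_features(labels, v), "F4", "theta_alpha")
  interior <- lab$label == "drowsy" & lab$episode > 1 & lab$episode < n_ep
  rate <- mean(lab$correlated[interior])
  n <- sum(interior)
  se <- sqrt((1 / 3 * 2 / 3 + 2 / 45) / n)  # lag-1 covariance of shared neighbours
  expect_lt(abs(rate - 1 / 3), 3 * se)
})

test_that("Spearman association is tie-corrected with a t-approximate p-value", {
  r1 <- spearman_association(c(10, 20, 30, 40), c(9, 19, 29, 39))
  expect_equal(r1$rho, 1)
  expect_equal(r1$p, 0)
  r2 <- spearman_association(c(10, 20, 30, 40), c(40, 30, 20, 10))
  expect_equal(r2$rho, -1)
  # ties: oracle = explicit average-rank computation
  x <- c(10, 20, 20, 30, 40)
  y <- c(5, 7, 7, 7, 9)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearman_association(x, y)
  expect_equal(got$rho, oracle)
  t_or <- oracle * sqrt(3 / (1 - oracle^2))
  expect_equal(got$p, 2 * pt(-abs(t_or), df = 3))
  expect_error(spearman_association(c(1, 2), c(3, 4)), "at least 3")
  expect_error(spearman_association(c(1, 1, 1), c(1, 2, 3)), "variance")
})
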