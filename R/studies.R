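# Canned simulation studies: the zero-effect (null) calibration check and
# the strong-effect sensitivity benchmark. Both run the full
# simulate -> filter -> feature -> concordance -> sensitivity chain and are
# used by the validation suite and the reproduction script alike.

#' Zero-effect null study
#'
#' Simulates a session whose drowsy and wake EEG are statistically
#' identical (zero effect), tiled into equal-length episodes, and measures
#' the fraction of interior drowsy episodes whose concordance criterion
#' holds for each feature. With exchangeable continuous feature values the
#' probability that the middle of three values is the extremum is exactly
#' 1/3, so every pass rate should sit within a few standard errors of 1/3.
#' Because consecutive drowsy episodes share a wake neighbour, pass events
#' have lag-1 covariance 2/15 - 1/9 = 1/45; the reported standard error
#' `sqrt((p(1-p) + 2/45)/n)` accounts for it.
#'
#' @param seed Integer seed.
#' @param n_interior_drowsy Number of interior drowsy episodes
#'   (default 2000).
#' @param episode_seconds Length of every episode in seconds (default 5;
#'   equal lengths make wake and drowsy feature values exchangeable).
#' @param channel Channel to analyse (default `"F4"`; one channel suffices
#'   under the null and keeps the run short).
#' @return Data frame with `feature`, `pass_rate`, `n`, `se`, `z`.
#' @export
run_null_study <- function(seed, n_interior_drowsy = 2000,
                           episode_seconds = 5, channel = "F4") {
  n_ep <- 2 * n_interior_drowsy + 1
  sched <- data.frame(
    label = rep(c("wake", "drowsy"), length.out = n_ep),
    start = (0:(n_ep - 1)) * episode_seconds,
    end = (1:n_ep) * episode_seconds)
  gain <- stats::setNames(1, channel)
  cfg <- sim_config(seed = seed, duration = n_ep * episode_seconds,
                    episode_schedule = sched, channels = channel,
                    channel_gain = gain, effect = "null")
  ses <- simulate_session(cfg)
  fm <- episode_features(design_apply_fir(ses$eeg), ses$truth$episodes)
  interior <- function(lab)
    lab$label == "drowsy" & lab$episode > 1 & lab$episode < n_ep
  p0 <- 1 / 3
  out <- do.call(rbind, lapply(feature_names(), function(f) {
    lab <- label_episodes(fm, channel, f)
    keep <- interior(lab)
    n <- sum(keep)
    rate <- mean(lab$correlated[keep])
    se <- sqrt((p0 * (1 - p0) + 2 / 45) / n)
    data.frame(feature = f, pass_rate = rate, n = n, se = se,
               z = (rate - p0) / se, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Strong-effect sensitivity study
#'
#' Simulates a cohort under the strong-effect condition (theta doubled,
#' delta 2.5x, alpha halved while drowsy) with a configurable per-channel
#' gain on the effect, runs the full feature/concordance/sensitivity
#' chain, and returns the cohort report. The default gain vector puts the
#' full effect on F4 and graded fractions elsewhere, so the per-channel
#' sensitivity ranking is identifiable (with every gain near 1 all
#' channels saturate at 100% and the ranking is a tie).
#'
#' @param seed Integer seed.
#' @param n_subjects Cohort size (default 3).
#' @param n_episodes Episodes per subject (default 200; wake 8-12 s,
#'   drowsy 5-9 s).
#' @param channel_gain Named per-channel multiplier on the drowsy effect.
#' @return List with `report` (a `sensitivity_report`), `features`
#'   (per-subject feature matrices) and `sessions`.
#' @export
run_strong_effect_study <- function(seed, n_subjects = 3, n_episodes = 200,
                                    channel_gain = c(F3 = 0.35, F4 = 1.0,
                                                     C3 = 0.15, C4 = 0.15,
                                                     O1 = 0.25, O2 = 0.5)) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
  sessions <- lapply(seq_len(n_subjects), function(i) {
    set.seed(seeds[i])
    len <- ifelse(seq_len(n_episodes) %% 2 == 1,
                  runif(n_episodes, 8, 12), runif(n_episodes, 5, 9))
    e <- cumsum(len)
    sched <- data.frame(label = rep(c("wake", "drowsy"), length.out = n_episodes),
                        start = c(0, head(e, -1)), end = e)
    cfg <- sim_config(seed = seeds[i], duration = ceiling(max(e)),
                      episode_schedule = sched, channel_gain = channel_gain)
    simulate_session(cfg)
  })
  names(sessions) <- paste0("subject", seq_len(n_subjects))
  fms <- lapply(sessions, function(s)
    episode_features(design_apply_fir(s$eeg), s$truth$episodes))
  list(report = build_report(fms), features = fms, sessions = sessions)
}
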