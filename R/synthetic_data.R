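# Coupled EAR + EEG session simulator with ground-truth episode structure.
#
# The generator emulates the study conditions: a 50-minute driving session
# alternating wakefulness (60-180 s) and drowsiness (20-90 s) segments;
# short Poisson-timed blinks while awake; long closures (2-6 s) reaching a
# target PERCLOS of ~0.4 while drowsy; and six-channel EEG whose per-band
# powers switch between wake and drowsy targets (theta and delta elevated,
# alpha suppressed while drowsy) with a per-channel gain on the drowsy
# effect and additive broadband noise. Band-limited components are white
# noise shaped in the frequency domain and rescaled so that the band power
# measured by the package's own Welch estimator matches the target
# (measure-and-rescale calibration).

#' Simulator configuration
#'
#' Defaults describe the emulated acquisition: 30 fps video, 200 Hz
#' six-channel EEG, 3000 s session. `band_power_drowsy` defaults to the
#' strong-effect condition (theta doubled, delta 2.5x, alpha halved,
#' beta unchanged, in signal-units squared); `effect = "null"` copies the
#' wake targets into the drowsy state so the two states are statistically
#' identical.
#'
#' @param seed Integer seed; the session is a deterministic function of it.
#' @param duration Session length in seconds (default 3000).
#' @param frame_rate Video frame rate, fps (default 30).
#' @param eeg_rate EEG sampling rate, Hz (default 200).
#' @param channels Channel labels (default the six 10-20 channels).
#' @param episode_schedule `"random"` (default) or an explicit data frame
#'   with columns `label`, `start`, `end` tiling `[0, duration]`.
#' @param wake_episode_range,drowsy_episode_range Uniform episode-length
#'   ranges in seconds for the random schedule (defaults 60-180 and 20-90).
#' @param wake_blink_rate Blinks per minute while awake (default 12).
#' @param wake_blink_duration Blink-duration range in seconds
#'   (default 0.1-0.3).
#' @param drowsy_closure_duration Closure-duration range in seconds while
#'   drowsy (default 2-6).
#' @param drowsy_closure_fraction Target closed-time fraction while drowsy
#'   (default 0.4).
#' @param open_ear,closed_ear EAR levels for open/closed eyes
#'   (defaults 0.32, 0.05).
#' @param ear_noise_sd Gaussian noise s.d. on the EAR trace (default 0.01).
#' @param band_power_wake,band_power_drowsy Named per-band power targets
#'   (delta/theta/alpha/beta, signal units squared).
#' @param channel_gain Named per-channel multiplier on the drowsy effect
#'   (default largest on F4, then O2).
#' @param eeg_noise_sd Broadband white-noise s.d. added per channel
#'   (default 0.5).
#' @param effect `"strong"` (default) keeps the drowsy targets; `"null"`
#'   replaces them with the wake targets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, duration = 3000, frame_rate = 30,
                       eeg_rate = 200, channels = EXPECTED_CHANNELS,
                       episode_schedule = "random",
                       wake_episode_range = c(60, 180),
                       drowsy_episode_range = c(20, 90),
                       wake_blink_rate = 12,
                       wake_blink_duration = c(0.1, 0.3),
                       drowsy_closure_duration = c(2, 6),
                       drowsy_closure_fraction = 0.4,
                       open_ear = 0.32, closed_ear = 0.05,
                       ear_noise_sd = 0.01,
                       band_power_wake = c(delta = 10, theta = 8, alpha = 12, beta = 6),
                       band_power_drowsy = c(delta = 25, theta = 16, alpha = 6, beta = 6),
                       channel_gain = c(F3 = 0.8, F4 = 1.0, C3 = 0.4,
                                        C4 = 0.4, O1 = 0.6, O2 = 0.9),
                       eeg_noise_sd = 0.5,
                       effect = c("strong", "null")) {
  effect <- match.arg(effect)
  if (effect == "null") band_power_drowsy <- band_power_wake
  if (duration <= 0 || frame_rate <= 0 || eeg_rate <= 0)
    stop("duration and rates must be positive")
  bands <- c("delta", "theta", "alpha", "beta")
  if (!all(bands %in% names(band_power_wake)) ||
      !all(bands %in% names(band_power_drowsy)))
    stop("band power targets must name delta, theta, alpha, beta")
  if (!all(channels %in% names(channel_gain)))
    stop("channel_gain must cover every channel")
  if (is.data.frame(episode_schedule)) {
    if (max(episode_schedule$end) > duration + 1e-9)
      stop("episode schedule exceeds the session duration")
  }
  structure(list(
    seed = seed, duration = duration, frame_rate = frame_rate,
    eeg_rate = eeg_rate, channels = channels,
    episode_schedule = episode_schedule,
    wake_episode_range = wake_episode_range,
    drowsy_episode_range = drowsy_episode_range,
    wake_blink_rate = wake_blink_rate,
    wake_blink_duration = wake_blink_duration,
    drowsy_closure_duration = drowsy_closure_duration,
    drowsy_closure_fraction = drowsy_closure_fraction,
    open_ear = open_ear, closed_ear = closed_ear,
    ear_noise_sd = ear_noise_sd,
    band_power_wake = band_power_wake,
    band_power_drowsy = band_power_drowsy,
    channel_gain = channel_gain, eeg_noise_sd = eeg_noise_sd,
    effect = effect), class = "sim_config")
}

# Alternating random schedule: wake first, truncated at `duration`.
.random_schedule <- function(config) {
  lab <- character(0); start <- numeric(0); end <- numeric(0)
  t <- 0; state <- "wake"
  while (t < config$duration) {
    r <- if (state == "wake") config$wake_episode_range else config$drowsy_episode_range
    len <- runif(1, r[1], r[2])
    e <- min(t + len, config$duration)
    lab <- c(lab, state); start <- c(start, t); end <- c(end, e)
    t <- e
    state <- if (state == "wake") "drowsy" else "wake"
  }
  # A truncated sliver at the end is merged backwards.
  n <- length(lab)
  if (n > 1 && end[n] - start[n] < 2) {
    end[n - 1] <- end[n]
    lab <- lab[-n]; start <- start[-n]; end <- end[-n]
  }
  data.frame(label = lab, start = start, end = end, stringsAsFactors = FALSE)
}

# Per-frame closed mask from the schedule.
.simulate_closures <- function(schedule, config) {
  fr <- config$frame_rate
  n <- round(config$duration * fr)
  closed <- logical(n)
  mark <- function(a, b) {
    i <- max(1L, floor(a * fr) + 1L); j <- min(n, ceiling(b * fr))
    if (j >= i) closed[i:j] <<- TRUE
  }
  for (k in seq_len(nrow(schedule))) {
    a <- schedule$start[k]; b <- schedule$end[k]
    if (schedule$label[k] == "wake") {
      t <- a + rexp(1, rate = config$wake_blink_rate / 60)
      while (t < b) {
        d <- runif(1, config$wake_blink_duration[1], config$wake_blink_duration[2])
        mark(t, min(t + d, b))
        t <- t + d + rexp(1, rate = config$wake_blink_rate / 60)
      }
    } else {
      f <- config$drowsy_closure_fraction
      mean_clos <- mean(config$drowsy_closure_duration)
      t <- a + runif(1, 0, 1)
      while (t < b) {
        d <- runif(1, config$drowsy_closure_duration[1],
                   config$drowsy_closure_duration[2])
        mark(t, min(t + d, b))
        gap <- runif(1, 0.5, 1.5) * mean_clos * (1 - f) / f
        t <- t + d + gap
      }
    }
  }
  closed
}

# EAR values from a closed mask: level switch, 2-frame ramps, noise.
.ear_from_mask <- function(closed, config) {
  lev <- ifelse(closed, config$closed_ear, config$open_ear)
  # 2-frame linear transitions into and out of closures
  sm <- stats::filter(lev, rep(1 / 2, 2), sides = 1)
  lev <- c(lev[1], as.numeric(sm[-1]))
  pmax(0, lev + rnorm(length(lev), 0, config$ear_noise_sd))
}

# Frequency-domain band-limited unit noise: white noise with all Fourier
# bins outside [lo, hi] zeroed, rescaled to unit variance. Work on a
# 2-3-5-smooth length (then truncate) so the FFT stays fast for any n.
.band_noise <- function(n, fs, lo, hi) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- fft(rnorm(m))
  f <- (0:(m - 1)) * fs / m
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  X[f < lo | f > hi] <- 0i
  x <- Re(fft(X, inverse = TRUE))[seq_len(n)] / m
  x / sqrt(mean(x^2))
}

#' Simulate one coupled EAR + EEG session
#'
#' Deterministic given `config$seed`. See [sim_config()] for the model.
#' The ground truth carries the episode table and, per channel, the
#' expected direction of each of the ten features under the configured
#' band-power targets (computed from idealised flat-in-band spectra with
#' the same formulas the feature extractor uses).
#'
#' @param config A [sim_config].
#' @return List with `ear` ([ear_trace]), `eeg` ([eeg_recording]) and
#'   `truth` (list: `episodes` ([episode_table]), `directions` data frame,
#'   `config`).
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seed <- sample.int(.Machine$integer.max - 1, 3)

  set.seed(sub_seed[1])
  schedule <- if (is.data.frame(config$episode_schedule)) config$episode_schedule
              else .random_schedule(config)

  set.seed(sub_seed[2])
  closed <- .simulate_closures(schedule, config)
  ear <- ear_trace(.ear_from_mask(closed, config), config$frame_rate)

  set.seed(sub_seed[3])
  fs <- config$eeg_rate
  n <- round(config$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  drowsy_mask <- logical(n)
  for (k in which(schedule$label == "drowsy"))
    drowsy_mask[tt >= schedule$start[k] & tt < schedule$end[k]] <- TRUE

  bands <- c("delta", "theta", "alpha", "beta")
  samples <- matrix(0, nrow = n, ncol = length(config$channels),
                    dimnames = list(NULL, config$channels))
  for (ch in config$channels) {
    g <- config$channel_gain[[ch]]
    units <- lapply(bands, function(b) {
      e <- band_edges(b)
      .band_noise(n, fs, e[1], e[2])
    })
    names(units) <- bands
    # Calibration loop-closure with the package's own estimator: measure
    # how much of each unit component the Welch integrator attributes to
    # every band (the Hann window leaks across band edges, mostly from
    # delta into theta) and solve for component powers such that the
    # *measured* per-band powers hit the targets.
    spectra <- lapply(units, function(u) welch_psd(u, fs))
    L <- sapply(spectra, function(s)
      vapply(bands, function(b) band_power_spec(s, band_edges(b)), 0))
    solve_scales <- function(targets) {
      s2 <- tryCatch(solve(L, targets), error = function(e) targets / diag(L))
      if (any(s2 <= 0)) s2 <- targets / diag(L)
      sqrt(s2)
    }
    tw <- vapply(bands, function(b) config$band_power_wake[[b]], 0)
    td <- tw + g * (vapply(bands, function(b) config$band_power_drowsy[[b]], 0) - tw)
    sw <- solve_scales(tw)
    sd_ <- solve_scales(td)
    acc <- rnorm(n, 0, config$eeg_noise_sd)
    for (k in seq_along(bands)) {
      env <- ifelse(drowsy_mask, sd_[k], sw[k])
      acc <- acc + units[[k]] * env
    }
    samples[, ch] <- acc
  }
  eeg <- eeg_recording(samples, fs)

  episodes <- episode_table(schedule$label, schedule$start, schedule$end)
  list(ear = ear, eeg = eeg,
       truth = list(episodes = episodes,
                    directions = .expected_directions(config),
                    config = config))
}

# Expected per-channel feature directions from idealised flat-in-band
# spectra with the configured targets.
.expected_directions <- function(config) {
  freqs <- seq(1, 30, by = 0.5)
  ideal_spec <- function(targets) {
    p <- numeric(length(freqs))
    for (b in c("delta", "theta", "alpha", "beta")) {
      e <- band_edges(b)
      keep <- freqs >= e[1] & freqs < e[2]
      p[keep] <- targets[[b]] / (e[2] - e[1])
    }
    spectrum_estimate(freqs, p)
  }
  feat10 <- function(spec) {
    pd <- band_power_spec(spec, band_edges("delta"))
    pt <- band_power_spec(spec, band_edges("theta"))
    pa <- band_power_spec(spec, band_edges("alpha"))
    c(psd_delta = pd, psd_theta = pt, psd_alpha = pa,
      theta_alpha = pt / pa, delta_alpha = pd / pa, delta_theta = pd / pt,
      spectral_entropy = spectral_entropy(spec),
      spectral_spread = spectral_spread(spec),
      spectral_centroid = spectral_centroid(spec),
      spectral_rolloff = spectral_rolloff(spec, 0.9))
  }
  wake <- feat10(ideal_spec(config$band_power_wake))
  out <- list()
  for (ch in config$channels) {
    g <- config$channel_gain[[ch]]
    dt <- config$band_power_wake +
      g * (config$band_power_drowsy[names(config$band_power_wake)] -
             config$band_power_wake)
    drow <- feat10(ideal_spec(as.list(dt)))
    out[[ch]] <- data.frame(
      channel = ch, feature = names(wake),
      direction = ifelse(drow > wake, "increases",
                         ifelse(drow < wake, "decreases", "none")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a cohort of subjects
#'
#' @param config A [sim_config]; per-subject seeds are derived from
#'   `config$seed`.
#' @param n_subjects Number of subjects.
#' @return Named list of sessions (`subject1`, `subject2`, ...).
#' @export
simulate_cohort <- function(config = sim_config(), n_subjects = 3) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_subjects)
  out <- lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    simulate_session(cfg)
  })
  names(out) <- paste0("subject", seq_len(n_subjects))
  out
}

#' Write the canonical small fixture files
#'
#' Writes (a) a short EAR trace containing a single blink, (b) a
#' three-episode wake/drowsy/wake session (EAR CSV, EEG as EDF and
#' delimited text, episode table CSV), and (c) a three-subject cohort of
#' short sessions. Deterministic given `seed`: running twice produces
#' identical bytes.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed (default 1).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  # (a) single-blink EAR trace: 4 s at 30 fps, one 5-frame blink
  set.seed(seed)
  v <- rep(0.32, 120)
  v[60:64] <- 0.06
  v <- pmax(0, v + rnorm(120, 0, 0.005))
  p <- file.path(out_dir, "ear_one_blink.csv")
  write_ear_trace(ear_trace(v, 30), p); add(p)

  # (b) three-episode session: wake 30 s, drowsy 12 s, wake 30 s
  sched <- data.frame(label = c("wake", "drowsy", "wake"),
                      start = c(0, 30, 42), end = c(30, 42, 72))
  ses <- simulate_session(sim_config(seed = seed + 1, duration = 72,
                                     episode_schedule = sched,
                                     drowsy_closure_fraction = 0.8))
  d <- file.path(out_dir, "session3"); dir.create(d, showWarnings = FALSE)
  p <- file.path(d, "ear.csv"); write_ear_trace(ses$ear, p); add(p)
  p <- file.path(d, "eeg.edf"); write_edf(ses$eeg, p); add(p)
  p <- file.path(d, "eeg.csv"); write_eeg_delimited(ses$eeg, p); add(p)
  p <- file.path(d, "episodes.csv"); write_episode_table(ses$truth$episodes, p); add(p)

  # (c) three-subject cohort, ten 6-12 s episodes each
  cohort_sched <- function() {
    lab <- rep(c("wake", "drowsy"), 5)
    len <- rep(c(10, 6), 5)
    e <- cumsum(len)
    data.frame(label = lab, start = c(0, head(e, -1)), end = e)
  }
  cohort <- simulate_cohort(
    sim_config(seed = seed + 2, duration = 80,
               episode_schedule = cohort_sched()), 3)
  for (nm in names(cohort)) {
    d <- file.path(out_dir, "cohort", nm)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(d, "ear.csv"); write_ear_trace(cohort[[nm]]$ear, p); add(p)
    p <- file.path(d, "eeg.csv"); write_eeg_delimited(cohort[[nm]]$eeg, p); add(p)
    p <- file.path(d, "episodes.csv")
    write_episode_table(cohort[[nm]]$truth$episodes, p); add(p)
  }
  invisible(files)
}
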