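# EEG preprocessing (equiripple FIR band limiting), episode slicing, and
# the ten per-episode, per-channel features.

#' FIR preprocessing configuration
#'
#' Both filters use the equiripple (Parks-McClellan) design. The low-pass
#' keeps the conventional order 25 (passband edge 30 Hz, 10 Hz transition),
#' which converges cleanly. A 1 Hz high-pass edge at a 200 Hz rate is not
#' realisable at order 25 — every such design has passband ripple above
#' 25% and essentially no DC attenuation — so the high-pass defaults to
#' its own order (350, stopband \[0, 0.5\] Hz, passband from 1 Hz,
#' passband-weighted 10:1), giving a flat EEG passband (±3%) and ~11 dB DC
#' rejection per pass (~22 dB after zero-phase application).
#'
#' @param fir_order Low-pass filter order (taps - 1; default 25).
#' @param hp_cutoff High-pass passband edge, Hz (default 1).
#' @param lp_cutoff Low-pass passband edge, Hz (default 30).
#' @param hp_transition High-pass transition width, Hz (default 0.5; the
#'   stopband ends at `hp_cutoff - hp_transition`).
#' @param lp_transition Low-pass transition width, Hz (default 10).
#' @param hp_order High-pass filter order (default 350).
#' @param hp_pass_weight Relative passband weight in the high-pass design
#'   (default 10).
#' @param zero_phase Apply each filter forward and backward (default TRUE),
#'   doubling the effective attenuation and preserving episode timing.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(fir_order = 25, hp_cutoff = 1, lp_cutoff = 30,
                              hp_transition = 0.5, lp_transition = 10,
                              hp_order = 350, hp_pass_weight = 10,
                              zero_phase = TRUE) {
  if (hp_cutoff <= 0 || lp_cutoff <= hp_cutoff)
    stop("need 0 < hp_cutoff < lp_cutoff")
  if (hp_transition <= 0 || hp_transition >= hp_cutoff)
    stop("hp_transition must lie in (0, hp_cutoff)")
  if (lp_transition <= 0) stop("lp_transition must be > 0")
  structure(list(fir_order = fir_order, hp_cutoff = hp_cutoff,
                 lp_cutoff = lp_cutoff, hp_transition = hp_transition,
                 lp_transition = lp_transition, hp_order = hp_order,
                 hp_pass_weight = hp_pass_weight, zero_phase = zero_phase),
            class = "preprocess_config")
}

#' Design the high-pass/low-pass FIR pair
#'
#' @param config A [preprocess_config].
#' @param sampling_rate Sampling rate in Hz.
#' @return List with numeric coefficient vectors `hp` and `lp`.
#' @export
design_fir <- function(config, sampling_rate) {
  nyq <- sampling_rate / 2
  if (config$lp_cutoff + config$lp_transition >= nyq)
    stop("low-pass stopband edge reaches the Nyquist frequency")
  hp <- as.numeric(signal::remez(
    config$hp_order,
    c(0, (config$hp_cutoff - config$hp_transition) / nyq,
      config$hp_cutoff / nyq, 1),
    c(0, 0, 1, 1),
    w = c(1, config$hp_pass_weight), density = 32))
  lp <- as.numeric(signal::remez(
    config$fir_order,
    c(0, config$lp_cutoff / nyq,
      (config$lp_cutoff + config$lp_transition) / nyq, 1),
    c(1, 1, 0, 0)))
  list(hp = hp, lp = lp)
}

#' Band-limit an EEG recording
#'
#' Applies the high-pass then the low-pass filter to every channel.
#' Zero-phase (forward-backward) application keeps episode boundaries
#' aligned with the video clock; a single-pass causal mode is available
#' via `zero_phase = FALSE` in the config.
#'
#' @param recording An [eeg_recording].
#' @param config A [preprocess_config].
#' @return A filtered [eeg_recording] of identical dimensions.
#' @export
design_apply_fir <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  filt <- design_fir(config, recording$sampling_rate)
  apply1 <- function(b, x) {
    if (config$zero_phase) as.numeric(signal::filtfilt(b, 1, x))
    else as.numeric(signal::filter(b, 1, x))
  }
  out <- recording$samples
  for (j in seq_len(ncol(out)))
    out[, j] <- apply1(filt$lp, apply1(filt$hp, out[, j]))
  eeg_recording(out, recording$sampling_rate, recording$start_time)
}

#' Slice an EEG recording by episode timestamps
#'
#' Episode times (seconds from session start, shifted by a constant
#' video-to-EEG clock offset) are mapped to sample indices by
#' `round(t * sampling_rate)`; adjacent episodes yield adjacent,
#' non-overlapping sample ranges.
#'
#' @param recording An [eeg_recording].
#' @param episodes An [episode_table].
#' @param offset Constant clock offset in seconds added to episode times
#'   (default 0).
#' @return A list (one element per episode) of matrices
#'   (samples x channels).
#' @export
slice_by_episode <- function(recording, episodes, offset = 0) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(episodes, "episode_table"))
  fs <- recording$sampling_rate
  n <- nrow(recording$samples)
  lapply(seq_len(nrow(episodes)), function(i) {
    a <- round((episodes$start[i] + offset) * fs)
    b <- round((episodes$end[i] + offset) * fs)
    if (a < 0 || b > n)
      stop("episode ", episodes$index[i], " lies outside the recording")
    recording$samples[(a + 1):b, , drop = FALSE]
  })
}

#' Feature-extraction configuration
#'
#' @param band_power_method `"welch"` (default; PSD integration over the
#'   printed band edges) or `"dwt"` (mean square of the dyadic band
#'   reconstructions after resampling to 60 Hz).
#' @param rolloff Rolloff fraction (default 0.9).
#' @param weights Spectral-moment weights: `"power"` (default) or
#'   `"magnitude"`.
#' @param fmin,fmax Analysis range in Hz for the spectral-shape features
#'   (defaults 1 and 30, the filtered passband).
#' @param seg_seconds Welch segment length in seconds (default 2; capped
#'   at the episode length).
#' @param min_length Minimum analyzable episode length in seconds
#'   (default 1); shorter episodes yield a row of `NA` features.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(band_power_method = c("welch", "dwt"),
                           rolloff = 0.9, weights = c("power", "magnitude"),
                           fmin = 1, fmax = 30, seg_seconds = 2,
                           min_length = 1) {
  structure(list(band_power_method = match.arg(band_power_method),
                 rolloff = rolloff, weights = match.arg(weights),
                 fmin = fmin, fmax = fmax, seg_seconds = seg_seconds,
                 min_length = min_length),
            class = "feature_config")
}

#' Names of the ten per-episode EEG features
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("psd_delta", "psd_theta", "psd_alpha",
    "theta_alpha", "delta_alpha", "delta_theta",
    "spectral_entropy", "spectral_spread", "spectral_centroid",
    "spectral_rolloff")
}

# All ten features for one segment (single channel).
.segment_features <- function(x, fs, config) {
  spec <- welch_psd(x, fs, seg_seconds = config$seg_seconds)
  if (config$band_power_method == "welch") {
    pd <- band_power_spec(spec, band_edges("delta"))
    pt <- band_power_spec(spec, band_edges("theta"))
    pa <- band_power_spec(spec, band_edges("alpha"))
  } else {
    pd <- band_power(x, fs, "delta", method = "dwt")
    pt <- band_power(x, fs, "theta", method = "dwt")
    pa <- band_power(x, fs, "alpha", method = "dwt")
  }
  s <- .spec_restrict(spec, config$fmin, config$fmax)
  c(psd_delta = pd, psd_theta = pt, psd_alpha = pa,
    theta_alpha = pt / pa, delta_alpha = pd / pa, delta_theta = pd / pt,
    spectral_entropy = spectral_entropy(s),
    spectral_spread = spectral_spread(s, config$weights),
    spectral_centroid = spectral_centroid(s, config$weights),
    spectral_rolloff = spectral_rolloff(s, config$rolloff, config$weights))
}

#' Per-episode, per-channel EEG feature matrix
#'
#' Computes the ten features (three band powers, three band-power ratios,
#' spectral entropy, spread, centroid, rolloff) for every
#' (episode, channel) pair. The recording should already be band-limited
#' (see [design_apply_fir()]).
#'
#' @param recording A filtered [eeg_recording].
#' @param episodes An [episode_table].
#' @param config A [feature_config].
#' @param offset Video-to-EEG clock offset in seconds (default 0).
#' @return Data frame with columns `episode`, `label`, `channel` and the
#'   ten feature columns of [feature_names()]. Episodes shorter than
#'   `config$min_length` get `NA` features.
#' @export
episode_features <- function(recording, episodes, config = feature_config(),
                             offset = 0) {
  segs <- slice_by_episode(recording, episodes, offset)
  fs <- recording$sampling_rate
  chans <- channel_labels(recording)
  fnames <- feature_names()
  rows <- vector("list", nrow(episodes) * length(chans))
  k <- 0
  for (i in seq_len(nrow(episodes))) {
    seg <- segs[[i]]
    too_short <- nrow(seg) < config$min_length * fs
    for (ch in chans) {
      k <- k + 1
      vals <- if (too_short) rep(NA_real_, length(fnames))
              else .segment_features(seg[, ch], fs, config)
      row <- data.frame(episode = episodes$index[i],
                        label = episodes$label[i], channel = ch,
                        stringsAsFactors = FALSE)
      row[fnames] <- as.list(unname(vals))
      rows[[k]] <- row
    }
  }
  do.call(rbind, rows)
}
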