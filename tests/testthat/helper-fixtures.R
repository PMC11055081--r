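# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Equal-length alternating schedule starting with wake.
alt_schedule <- function(n_ep, episode_seconds = 5) {
  data.frame(label = rep(c("wake", "drowsy"), length.out = n_ep),
             start = (0:(n_ep - 1)) * episode_seconds,
             end = (1:n_ep) * episode_seconds)
}

# Small feature matrix with one feature column filled in, for concordance
# tests: `values` is a per-episode vector, replicated per channel unless a
# per-channel list is given.
toy_features <- function(labels, values, feature = "theta_alpha",
                         channels = "F4") {
  if (!is.list(values)) values <- stats::setNames(
    rep(list(values), length(channels)), channels)
  do.call(rbind, lapply(channels, function(ch) {
    df <- data.frame(episode = seq_along(labels), label = labels,
                     channel = ch, stringsAsFactors = FALSE)
    for (f in feature_names()) df[[f]] <- NA_real_
    df[[feature]] <- values[[ch]]
    df
  }))
}

# Tiny deterministic EEG recording: named sinusoids plus noise.
toy_recording <- function(n_seconds = 10, fs = 200, channels = c("F3", "F4"),
                          seed = 42) {
  set.seed(seed)
  t <- (0:(n_seconds * fs - 1)) / fs
  samples <- sapply(channels, function(ch)
    sin(2 * pi * 10 * t) + 0.1 * rnorm(length(t)))
  eeg_recording(samples, fs)
}
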