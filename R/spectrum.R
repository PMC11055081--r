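# Welch power-spectral-density estimation and the four spectral-shape
# features (entropy, centroid, spread, rolloff).

#' Welch power spectral density estimate
#'
#' Hann-windowed, overlapping-segment averaged periodogram. The density is
#' one-sided and scaled so that `sum(power) * df` equals the signal's mean
#' square (a unit-amplitude sinusoid integrates to ~0.5).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param seg_seconds Segment length in seconds; capped at the signal
#'   length (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param detrend Subtract each segment's mean before windowing
#'   (default TRUE).
#' @param nfft_factor Zero-padding factor: segments are padded to
#'   `nfft_factor` times the window length before the FFT (default 4),
#'   interpolating the spectrum onto a finer grid so bin-quantised
#'   statistics (notably the rolloff) behave like their continuous
#'   counterparts.
#' @return An object of class `spectrum_estimate`: list with `freqs` (Hz,
#'   uniform spacing), `power` (density, units^2/Hz), `df` (bin width),
#'   `bin_count`.
#' @export
welch_psd <- function(x, fs, seg_seconds = 2, overlap = 0.5, detrend = TRUE,
                      nfft_factor = 4) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("signal too short for a PSD estimate")
  L <- min(n, max(8L, round(seg_seconds * fs)))
  nfft <- L * max(1L, as.integer(nfft_factor))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)   # periodic Hann
  u <- sum(w^2)
  nb <- floor(nfft / 2) + 1L
  acc <- numeric(nb)
  pad <- numeric(nfft - L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(c(w * seg, pad))[seq_len(nb)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  p <- acc / length(starts)
  # one-sided: double every bin except DC (and Nyquist when nfft even)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nb] <- 1
  p <- p * dbl
  structure(list(freqs = (0:(nb - 1L)) * fs / nfft, power = p,
                 df = fs / nfft, bin_count = nb),
            class = "spectrum_estimate")
}

#' Construct a spectrum estimate from explicit bins
#'
#' Convenience constructor used when a spectrum is specified directly
#' (e.g. in tests or when the PSD comes from another estimator).
#'
#' @param freqs Strictly increasing, uniformly spaced frequencies (Hz).
#' @param power Non-negative per-bin density values.
#' @return A `spectrum_estimate`.
#' @export
spectrum_estimate <- function(freqs, power) {
  freqs <- as.numeric(freqs); power <- as.numeric(power)
  if (length(freqs) != length(power)) stop("freqs and power must match")
  if (length(freqs) > 1 && any(diff(freqs) <= 0))
    stop("freqs must be strictly increasing")
  if (any(power < 0)) stop("power must be non-negative")
  df <- if (length(freqs) > 1) freqs[2] - freqs[1] else 1
  structure(list(freqs = freqs, power = power, df = df,
                 bin_count = length(freqs)),
            class = "spectrum_estimate")
}

# Restrict a spectrum to [lo, hi] (inclusive).
.spec_restrict <- function(spec, lo, hi) {
  keep <- spec$freqs >= lo & spec$freqs <= hi
  spectrum_estimate(spec$freqs[keep], spec$power[keep])
}

# Per-bin weights for the centroid/spread/rolloff family.
.spec_weights <- function(spec, weights = c("power", "magnitude")) {
  weights <- match.arg(weights)
  if (weights == "power") spec$power else sqrt(spec$power)
}

#' Band power
#'
#' `method = "welch"` integrates a Welch PSD over `[lo, hi)`;
#' `method = "dwt"` takes the mean square of the matching dyadic band
#' reconstruction of a level-3 db2 decomposition (the segment is resampled
#' to 60 Hz first so the dyadic bands line up with the EEG bands).
#'
#' @param x Numeric signal segment.
#' @param fs Sampling rate of `x` in Hz.
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`) or a
#'   numeric `c(lo, hi)` in Hz (welch method only).
#' @param method `"welch"` (default) or `"dwt"`.
#' @param seg_seconds Welch segment length in seconds.
#' @return Non-negative power (signal units squared).
#' @export
band_power <- function(x, fs, band, method = c("welch", "dwt"),
                       seg_seconds = 2) {
  method <- match.arg(method)
  if (method == "welch") {
    edges <- if (is.character(band)) band_edges(band) else as.numeric(band)
    if (edges[2] > fs / 2) stop("band extends beyond the Nyquist frequency")
    spec <- welch_psd(x, fs, seg_seconds = seg_seconds)
    return(band_power_spec(spec, edges))
  }
  if (!is.character(band))
    stop("the dwt method uses named dyadic bands")
  y <- resample_for_dwt(x, from = fs, to = 60)
  dec <- dwt_decompose(y, dwt_rate = 60)
  r <- dec$reconstruction[[band]]
  if (is.null(r)) stop("unknown band: ", band)
  mean(r^2)
}

#' Integrate a PSD over a band
#'
#' @param spec A `spectrum_estimate`.
#' @param edges Numeric `c(lo, hi)` in Hz; bins with `lo <= f < hi`.
#' @return Integrated power.
#' @export
band_power_spec <- function(spec, edges) {
  keep <- spec$freqs >= edges[1] & spec$freqs < edges[2]
  sum(spec$power[keep]) * spec$df
}

#' Conventional EEG band edges
#'
#' delta 1-4, theta 4-7.5, alpha 7.5-15, beta 15-30 Hz.
#'
#' @param name Band name.
#' @return Numeric `c(lo, hi)` in Hz.
#' @export
band_edges <- function(name) {
  switch(name,
         delta = c(1, 4), theta = c(4, 7.5), alpha = c(7.5, 15),
         beta = c(15, 30),
         stop("unknown band: ", name))
}

#' Spectral entropy (bits)
#'
#' Shannon entropy of the normalised PSD: `H = -sum(n_f * log2(n_f))`
#' with `n_f = power_f / sum(power)`. Zero-power bins contribute 0;
#' `0 <= H <= log2(L)` over `L` bins. No normalisation by `log2(L)` is
#' applied.
#'
#' @param spec A `spectrum_estimate`.
#' @return Entropy in bits.
#' @export
spectral_entropy <- function(spec) {
  p <- spec$power
  tot <- sum(p)
  if (tot <= 0) stop("spectral entropy of an all-zero spectrum is undefined")
  nf <- p / tot
  nz <- nf > 0
  -sum(nf[nz] * log2(nf[nz]))
}

#' Spectral centroid (Hz)
#'
#' Weighted mean frequency `C = sum(f_k X_k) / sum(X_k)`; weights are the
#' PSD values by default, or their square roots with
#' `weights = "magnitude"`.
#'
#' @param spec A `spectrum_estimate`.
#' @param weights `"power"` (default) or `"magnitude"`.
#' @return Centroid in Hz, within the bin frequency range.
#' @export
spectral_centroid <- function(spec, weights = "power") {
  X <- .spec_weights(spec, weights)
  tot <- sum(X)
  if (tot <= 0) stop("spectral centroid of an all-zero spectrum is undefined")
  sum(spec$freqs * X) / tot
}

#' Spectral spread (Hz)
#'
#' Weighted standard deviation of frequency around the centroid:
#' `S = sqrt(sum((f_k - C)^2 X_k) / sum(X_k))`; 0 iff a single bin carries
#' all the weight.
#'
#' @inheritParams spectral_centroid
#' @return Spread in Hz (>= 0).
#' @export
spectral_spread <- function(spec, weights = "power") {
  X <- .spec_weights(spec, weights)
  tot <- sum(X)
  if (tot <= 0) stop("spectral spread of an all-zero spectrum is undefined")
  C <- sum(spec$freqs * X) / tot
  sqrt(sum((spec$freqs - C)^2 * X) / tot)
}

#' Spectral rolloff (Hz)
#'
#' Frequency of the smallest bin `m` whose cumulative weight reaches
#' fraction `C` of the total; monotone non-decreasing in `C`.
#'
#' @inheritParams spectral_centroid
#' @param C Rolloff fraction in (0, 1\] (default 0.9).
#' @return Rolloff frequency in Hz.
#' @export
spectral_rolloff <- function(spec, C = 0.9, weights = "power") {
  if (C <= 0 || C > 1) stop("rolloff fraction C must be in (0, 1]")
  X <- .spec_weights(spec, weights)
  tot <- sum(X)
  if (tot <= 0) stop("spectral rolloff of an all-zero spectrum is undefined")
  m <- which(cumsum(X) >= C * tot - 1e-12)[1]
  spec$freqs[m]
}
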