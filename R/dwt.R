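# Periodised orthogonal discrete wavelet transform with the Daubechies
# db2 (4-tap) wavelet, to decomposition level 3. With an orthonormal
# filter pair and periodic (circular) extension the transform is an
# orthogonal matrix: reconstruction is exact and coefficient energy equals
# signal energy (Parseval). Signals whose length is not a multiple of 2^3
# are extended periodically to the next multiple; band reconstructions are
# trimmed back, which preserves exact reconstruction of the original
# samples.

# db2 orthonormal scaling (low-pass) filter; sum of squares = 1.
.db2_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
# Quadrature-mirror high-pass: g[n] = (-1)^n h[L-1-n].
.db2_g <- c(.db2_h[4], -.db2_h[3], .db2_h[2], -.db2_h[1])

# One analysis step, periodic extension; the sampling phase matches the
# standard periodised convolution (a[k] = sum_m h[m] x[2k - 1 + m]), so
# coefficients agree with the usual db2 periodisation convention.
# Returns list(a, d), each length N/2.
.dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2 != 0) stop("periodised DWT step requires even length")
  k2 <- seq(0, n - 2, by = 2)
  a <- numeric(n / 2); d <- numeric(n / 2)
  for (m in 0:3) {
    idx <- (k2 + m - 1) %% n + 1
    a <- a + .db2_h[m + 1] * x[idx]
    d <- d + .db2_g[m + 1] * x[idx]
  }
  list(a = a, d = d)
}

# One synthesis step (exact transpose of the analysis step).
.idwt_step <- function(a, d) {
  n <- 2 * length(a)
  x <- numeric(n)
  k2 <- seq(0, n - 2, by = 2)
  for (m in 0:3) {
    idx <- (k2 + m - 1) %% n + 1
    contrib <- .db2_h[m + 1] * a + .db2_g[m + 1] * d
    # scatter-add; idx values are unique within one m
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Level-3 db2 wavelet decomposition with band mapping
#'
#' Decomposes a segment into detail coefficients D1-D3 and approximation
#' A3 and reconstructs the four corresponding band-limited time series.
#' At a 60 Hz decomposition rate the dyadic bands line up with the
#' conventional EEG bands: D1 -> beta (15-30 Hz), D2 -> alpha (7.5-15 Hz),
#' D3 -> theta (3.75-7.5 Hz), A3 -> delta (0-3.75 Hz); the 3.75 Hz dyadic
#' edge approximates the printed 4 Hz theta/delta boundary.
#'
#' @param segment Numeric vector, length >= 8.
#' @param dwt_rate Sampling rate in Hz of the decomposed signal
#'   (default 60; see [resample_for_dwt()]).
#' @return A list of class `band_decomposition` with `coefficients`
#'   (list `D1`, `D2`, `D3`, `A3`), `reconstruction` (list `beta`, `alpha`,
#'   `theta`, `delta`, each trimmed to the input length), `bands` (data
#'   frame of dyadic band edges), `dwt_rate`, and `n` (input length).
#' @export
dwt_decompose <- function(segment, dwt_rate = 60) {
  x <- as.numeric(segment)
  n <- length(x)
  if (n < 8) stop("segment too short for a level-3 decomposition (need >= 8 samples)")
  n_pad <- 8 * ceiling(n / 8)
  if (n_pad > n) x <- c(x, x[seq_len(n_pad - n)])  # periodic wrap

  s1 <- .dwt_step(x)
  s2 <- .dwt_step(s1$a)
  s3 <- .dwt_step(s2$a)
  coefs <- list(D1 = s1$d, D2 = s2$d, D3 = s3$d, A3 = s3$a)

  zero <- function(v) numeric(length(v))
  recon_from <- function(a3, d3, d2, d1) {
    a2 <- .idwt_step(a3, d3)
    a1 <- .idwt_step(a2, d2)
    .idwt_step(a1, d1)[seq_len(n)]
  }
  recon <- list(
    beta  = recon_from(zero(s3$a), zero(s3$d), zero(s2$d), s1$d),
    alpha = recon_from(zero(s3$a), zero(s3$d), s2$d, zero(s1$d)),
    theta = recon_from(zero(s3$a), s3$d, zero(s2$d), zero(s1$d)),
    delta = recon_from(s3$a, zero(s3$d), zero(s2$d), zero(s1$d))
  )
  nyq <- dwt_rate / 2
  bands <- data.frame(
    name = c("beta", "alpha", "theta", "delta"),
    set  = c("D1", "D2", "D3", "A3"),
    lo   = c(nyq / 2, nyq / 4, nyq / 8, 0),
    hi   = c(nyq, nyq / 2, nyq / 4, nyq / 8),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, reconstruction = recon, bands = bands,
                 dwt_rate = dwt_rate, n = n, n_pad = n_pad,
                 padded = x),
            class = "band_decomposition")
}

#' Resample a segment for dyadic band analysis
#'
#' Anti-aliased polyphase resampling (rational factor) used to bring a
#' 200 Hz EEG segment to 60 Hz, where the level-3 dyadic band edges of
#' [dwt_decompose()] match the conventional EEG band boundaries.
#'
#' @param x Numeric vector.
#' @param from Source rate in Hz.
#' @param to Target rate in Hz (default 60).
#' @return Resampled numeric vector of length `ceiling(length(x) * to/from)`.
#' @export
resample_for_dwt <- function(x, from, to = 60) {
  if (from == to) return(as.numeric(x))
  ratio <- to / from
  # smallest integer p/q representation
  f <- .rational(ratio)
  as.numeric(signal::resample(as.numeric(x), f$p, f$q))
}

.rational <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("cannot represent resampling ratio ", r, " as a small rational")
}
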