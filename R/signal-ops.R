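# Low-level signal primitives: fractional delay, band-limited noise and
# time-frequency concentrated bursts.  All spectral surgery is done with the
# FFT; at 4 kHz every chest-scale propagation delay is a small fraction of a
# sample, so integer shifting would be a no-op and all delays are applied as
# frequency-domain phase rotations (exact for band-limited signals).

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# Flat-topped cosine-tapered (Tukey) window; alpha is the total taper
# fraction.  alpha = 1 reduces to Hann, alpha = 0 to rectangular.
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

# Apply several fractional-sample delays to one signal with a single
# forward FFT.  Returns a matrix with one row per shift.
fractional_shift_multi <- function(x, shifts) {
  n <- length(x)
  npad <- ceiling(max(abs(shifts), 1)) + 8L
  nfft <- stats::nextn(n + 2L * npad, c(2, 3, 5))
  xp <- c(numeric(npad), x, numeric(nfft - n - npad))
  xf <- stats::fft(xp)
  k <- 0:(nfft - 1)
  f <- ifelse(k <= nfft / 2, k, k - nfft) / nfft
  out <- matrix(0, length(shifts), n)
  for (i in seq_along(shifts)) {
    h <- exp(-2i * pi * f * shifts[i])
    if (nfft %% 2 == 0) h[nfft / 2 + 1] <- Re(h[nfft / 2 + 1])
    y <- Re(stats::fft(xf * h, inverse = TRUE)) / nfft
    out[i, ] <- y[(npad + 1):(npad + n)]
  }
  out
}

# Delay each row of `samples` by its shift and sum, accumulating in the
# frequency domain (one inverse FFT instead of one per channel).
delay_sum_multi <- function(samples, shifts) {
  n <- ncol(samples)
  npad <- ceiling(max(abs(shifts), 1)) + 8L
  nfft <- stats::nextn(n + 2L * npad, c(2, 3, 5))
  k <- 0:(nfft - 1)
  f <- ifelse(k <= nfft / 2, k, k - nfft) / nfft
  acc <- complex(nfft)
  for (i in seq_len(nrow(samples))) {
    xp <- c(numeric(npad), samples[i, ], numeric(nfft - n - npad))
    h <- exp(-2i * pi * f * shifts[i])
    if (nfft %% 2 == 0) h[nfft / 2 + 1] <- Re(h[nfft / 2 + 1])
    acc <- acc + stats::fft(xp) * h
  }
  y <- Re(stats::fft(acc, inverse = TRUE)) / nfft
  y[(npad + 1):(npad + n)]
}

#' Shift a signal by a fractional number of samples
#'
#' Applies a pure delay (positive `shift`) or advance (negative `shift`) via
#' frequency-domain phase rotation.  The record is zero-padded before the
#' circular shift so that samples moved past either edge are zero-filled
#' rather than wrapped.
#'
#' @param x Numeric vector.
#' @param shift Shift in samples; may be fractional.
#' @return Numeric vector of the same length as `x`.
#' @keywords internal
fractional_shift <- function(x, shift) {
  if (shift == 0) return(x)
  n <- length(x)
  npad <- ceiling(abs(shift)) + 8L
  nfft <- stats::nextn(n + 2L * npad, c(2, 3, 5))
  xp <- c(numeric(npad), x, numeric(nfft - n - npad))
  k <- 0:(nfft - 1)
  f <- ifelse(k <= nfft / 2, k, k - nfft) / nfft  # cycles per sample
  h <- exp(-2i * pi * f * shift)
  if (nfft %% 2 == 0) h[nfft / 2 + 1] <- Re(h[nfft / 2 + 1])
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / nfft
  y[(npad + 1):(npad + n)]
}

# Stationary Gaussian noise brick-walled to `band` (Hz), unit RMS.
band_noise <- function(n, band, fs) {
  w <- stats::rnorm(n)
  wf <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  wf[!(f >= band[1] & f <= band[2])] <- 0 + 0i
  x <- Re(stats::fft(wf, inverse = TRUE)) / n
  r <- rms(x)
  if (r > 0) x / r else x
}

# A bank of `nb` independent unit-RMS noise bursts, each `nd` samples long,
# spectrally confined to `band`.  Starting from Hann-windowed band-limited
# noise, a few alternating projections between the band constraint and the
# envelope constraint push the out-of-band energy leakage of the finite
# burst below a few percent (the time-bandwidth products used here admit
# well-concentrated functions) while keeping the time support exact: the
# envelope is applied last, so sample 1 is the true onset.
burst_bank <- function(nb, nd, band, fs, iters = 8L, ngrid = NULL,
                       envelope = c("hann", "tukey"), tukey_alpha = 0.25) {
  envelope <- match.arg(envelope)
  if (nb == 0L) return(matrix(numeric(0), nd, 0))
  if (is.null(ngrid)) ngrid <- max(2048L, stats::nextn(2L * nd, 2))
  env <- switch(envelope,
                hann = hann_window(nd),
                tukey = tukey_window(nd, tukey_alpha))
  k <- 0:(ngrid - 1)
  f <- pmin(k, ngrid - k) * fs / ngrid
  keep <- f >= band[1] & f <= band[2]
  wf <- stats::mvfft(matrix(stats::rnorm(ngrid * nb), ngrid, nb))
  wf[!keep, ] <- 0 + 0i
  x <- Re(stats::mvfft(wf, inverse = TRUE))[1:nd, , drop = FALSE] / ngrid
  x <- x * env
  z <- matrix(0, ngrid, nb)
  for (it in seq_len(iters)) {
    z[1:nd, ] <- x
    zf <- stats::mvfft(z)
    zf[!keep, ] <- 0 + 0i
    x <- Re(stats::mvfft(zf, inverse = TRUE))[1:nd, , drop = FALSE] / ngrid
    x <- x * env
  }
  scale <- sqrt(colMeans(x^2))
  scale[scale == 0] <- 1
  sweep(x, 2, scale, "/")
}
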