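# Per-segment features: approximate entropy and the 150-Hz band-energy
# ratio.

#' Approximate entropy of a short time series
#'
#' Computes `ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r)` with
#' `Phi^m(r) = sum_i ln C_r^m(i) / (N - m + 1)`, where `C_r^m(i)` is the
#' fraction of length-`m` template vectors within Chebyshev distance `r`
#' of template `i`.  Self-matches are counted by default, so `C > 0` and
#' the estimate is non-negative (up to numerical tolerance).  Higher
#' values indicate a less regular, less predictable series.
#'
#' The tolerance defaults to `r_coefficient` times the sample standard
#' deviation of the series as supplied (i.e. after any normalization and
#' filtering applied upstream), which makes the statistic invariant to
#' positive amplitude scaling.  A constant series has `SD = 0`, hence
#' `r = 0`; the `<= r` match rule then still matches every identical
#' template and returns exactly 0.
#'
#' @param x Numeric vector (or `pcg_segment`) with at least `m + 2`
#'   samples.
#' @param m Embedding dimension (default 2).
#' @param r_coefficient Tolerance as a fraction of `sd(x)` (default 0.1);
#'   ignored when `r` is given.
#' @param r Absolute tolerance; overrides `r_coefficient`.
#' @param self_match Count the self comparison `j = i` (default `TRUE`).
#'   With `FALSE`, a template with no neighbour makes the estimate
#'   undefined (`NA` with a warning).
#' @param phi_m1_count Number of template vectors used as the denominator
#'   of `C` at length `m + 1`: `"n_minus_m"` (the `N - (m+1) + 1` of the
#'   defining formula, default) or `"n_minus_m_plus_1"`.
#' @return Approximate entropy (dimensionless scalar).
#' @export
approximate_entropy <- function(x, m = 2L, r_coefficient = 0.1, r = NULL,
                                self_match = TRUE,
                                phi_m1_count = c("n_minus_m",
                                                 "n_minus_m_plus_1")) {
  phi_m1_count <- match.arg(phi_m1_count)
  if (inherits(x, "pcg_segment")) x <- x$samples
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  if (m < 1L) stop_pcg("pcgbeam_config_error", "`m` must be >= 1")
  if (n <= m + 1L) {
    stop_pcg("pcgbeam_input_error",
             "need more than m + 1 = %d samples, got %d", m + 1L, n)
  }
  if (is.null(r)) {
    check_number(r_coefficient, "r_coefficient", lower = 0,
                 strict_lower = TRUE)
    r <- r_coefficient * stats::sd(x)
  }
  check_number(r, "r", lower = 0)
  out <- apen_kernel(x, m, r, isTRUE(self_match),
                     phi_m1_count == "n_minus_m_plus_1")
  if (is.na(out)) {
    warning("a template vector has no neighbour within r; ApEn undefined ",
            "without self-matches")
  }
  out
}

#' One-sided power spectrum of a segment
#'
#' Plain FFT periodogram (rectangular window by default; the downstream
#' ratio statistic integrates broad bands, so leakage across the 150-Hz
#' split is second order).  Power is scaled so that the sum over all bins
#' equals the mean-square energy of the (windowed) segment -- the discrete
#' Parseval identity.
#'
#' @param segment A `pcg_segment` or numeric vector.
#' @param sample_rate Samples per second (taken from the segment when
#'   available).
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return A list of class `pcg_spectrum` with `frequency` (Hz, from 0 to
#'   the Nyquist) and `power`.
#' @export
power_spectrum <- function(segment, sample_rate = NULL,
                           window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (inherits(segment, "pcg_segment")) {
    if (is.null(sample_rate)) sample_rate <- segment$sample_rate
    x <- segment$samples
  } else {
    x <- as.numeric(segment)
    if (is.null(sample_rate)) sample_rate <- PCG_SAMPLE_RATE
  }
  n <- length(x)
  if (window == "hann") x <- x * hann_window(n)
  xf <- stats::fft(x)
  half <- floor(n / 2)
  p_all <- Mod(xf)^2 / n^2
  idx <- 1:(half + 1)                       # bins 0 .. Nyquist
  power <- p_all[idx]
  dbl <- 2:(half + if (n %% 2 == 0) 0 else 1)
  power[dbl] <- 2 * power[dbl]              # fold negative frequencies
  structure(list(frequency = (idx - 1) * sample_rate / n,
                 power = power, n = n, sample_rate = sample_rate,
                 window = window),
            class = "pcg_spectrum")
}

#' Band-energy ratio about a split frequency
#'
#' Computes `Ratio = energy above the split / energy below the split`
#' within the analysis band: the numerator sums spectral power in bins
#' with centre frequency strictly above `split_hz` (up to the band top),
#' the denominator in bins at or below `split_hz` (down to the band
#' bottom).  Bins outside the analysis band are excluded.  A bin centred
#' exactly on the split counts as "below".
#'
#' @param spectrum A `pcg_spectrum` from [power_spectrum()].
#' @param split_hz Split frequency (default 150 Hz).
#' @param band Analysis band (default 65-500 Hz, the pass band of the
#'   preprocessing filter).
#' @return A list with `ratio`, `energy_below`, `energy_above` and
#'   `degenerate` (`TRUE` when the denominator is exactly zero and the
#'   ratio is reported as `Inf`).
#' @export
band_energy_ratio <- function(spectrum, split_hz = 150, band = c(65, 500)) {
  stopifnot(inherits(spectrum, "pcg_spectrum"))
  f <- spectrum$frequency
  p <- spectrum$power
  below <- f >= band[1] & f <= split_hz
  above <- f > split_hz & f <= band[2]
  energy_below <- sum(p[below])
  energy_above <- sum(p[above])
  degenerate <- energy_below == 0
  list(ratio = if (degenerate) Inf else energy_above / energy_below,
       energy_below = energy_below, energy_above = energy_above,
       degenerate = degenerate)
}

#' All per-segment features
#'
#' @param segment A `pcg_segment` (typically normalized and filtered).
#' @param m,r_coefficient Approximate-entropy parameters.
#' @param split_hz,band Band-energy-ratio parameters.
#' @return One-row data frame: `subject_id`, `condition`, `cycle_index`,
#'   `apen`, `ratio`, `energy_below_150`, `energy_above_150`.
#' @export
segment_features <- function(segment, m = 2L, r_coefficient = 0.1,
                             split_hz = 150, band = c(65, 500)) {
  stopifnot(inherits(segment, "pcg_segment"))
  feature_block(list(segment), m = m, r_coefficient = r_coefficient,
                split_hz = split_hz, band = band)
}

# Feature rows for a list of segments, built columnwise (one data.frame
# allocation for the whole block).
feature_block <- function(segments, m = 2L, r_coefficient = 0.1,
                          split_hz = 150, band = c(65, 500)) {
  ns <- length(segments)
  apen <- ratio <- e_below <- e_above <- numeric(ns)
  for (i in seq_len(ns)) {
    seg <- segments[[i]]
    sp <- power_spectrum(seg)
    ber <- band_energy_ratio(sp, split_hz = split_hz, band = band)
    apen[i] <- approximate_entropy(seg$samples, m = m,
                                   r_coefficient = r_coefficient)
    ratio[i] <- ber$ratio
    e_below[i] <- ber$energy_below
    e_above[i] <- ber$energy_above
  }
  data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    condition = vapply(segments, `[[`, character(1), "condition"),
    cycle_index = vapply(segments, `[[`, numeric(1), "cycle_index"),
    apen = apen, ratio = ratio,
    energy_below_150 = e_below, energy_above_150 = e_above,
    stringsAsFactors = FALSE
  )
}
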