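# Independent oracles used by the tests.  These are deliberately plain
# transcriptions of the defining formulas, kept separate from the package
# implementation they check.

# Literal O(N^2) approximate entropy:
#   C_r^m(i) = N_r^m(i) / (N - m + 1),  i = 1 .. N - m + 1
#   Phi^m(r) = sum_i ln C_r^m(i) / (N - m + 1)
#   ApEn     = Phi^m - Phi^(m+1)
# with d[X(i), X(j)] the maximum absolute coordinate difference and the
# match rule d <= r (self comparison included).  The loop over i is
# explicit; the j loop computes d for all j via running elementwise maxima.
apen_bruteforce <- function(x, m = 2L, r = NULL, r_coefficient = 0.1) {
  n <- length(x)
  if (is.null(r)) r <- r_coefficient * sd(x)
  phi <- function(mm) {
    n_vec <- n - mm + 1L
    log_c <- numeric(n_vec)
    for (i in seq_len(n_vec)) {
      d <- abs(x[i] - x[seq_len(n_vec)])
      if (mm > 1) {
        for (k in seq_len(mm - 1L)) {
          d <- pmax(d, abs(x[i + k] - x[seq_len(n_vec) + k]))
        }
      }
      log_c[i] <- log(sum(d <= r) / n_vec)
    }
    sum(log_c) / n_vec
  }
  phi(m) - phi(m + 1L)
}

# Sub-sample lag between two copies of one band-limited signal, estimated
# from the phase of the cross-spectrum (weighted linear fit of phase vs
# frequency over high-energy bins).
phase_lag_seconds <- function(a, b, fs) {
  n <- length(a)
  af <- fft(a)
  bf <- fft(b)
  cross <- af * Conj(bf)
  k <- 1:(floor(n / 2) - 1)           # skip DC and Nyquist
  w <- 2 * pi * k * fs / n            # rad/s
  ph <- Arg(cross[k + 1])
  wt <- Mod(cross[k + 1])
  keep <- wt > max(wt) * 1e-3
  -sum(wt[keep] * ph[keep] * w[keep]) / sum(wt[keep] * w[keep]^2)
}

# Permutation p-value for a one-way layout: proportion of label
# permutations whose F statistic reaches the observed one.
permutation_anova_p <- function(groups, n_perm = 10000, seed = 1) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  f_of <- function(lab) {
    means <- tapply(x_perm, lab, mean)
    ns <- tapply(x_perm, lab, length)
    ssb <- sum(ns * (means - mean(x_perm))^2)
    ssw <- sum((x_perm - means[lab])^2)
    (ssb / (length(groups) - 1)) / (ssw / (length(x_perm) - length(groups)))
  }
  x_perm <- x
  f_obs <- f_of(idx)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    lab <- sample(idx)
    if (f_of(lab) >= f_obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Energy fraction of `x` inside `band`, by Parseval on the full FFT grid.
inband_energy_fraction <- function(x, band, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  sum(p[f >= band[1] & f <= band[2]]) / sum(p)
}
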