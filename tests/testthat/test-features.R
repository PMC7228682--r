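test_that("approximate entropy matches the literal quadratic oracle", {
  set.seed(41)
  cases <- list(
    alternating = rep_len(c(0, 1), 64),
    uniform512 = runif(512),
    gaussian128 = rnorm(128),
    sine_plus_noise = sin(2 * pi * 5 * (0:255) / 256) + 0.1 * rnorm(256),
    ar1 = as.numeric(stats::filter(rnorm(200), 0.9, "recursive"))
  )
  for (nm in names(cases)) {
    x <- cases[[nm]]
    expect_equal(approximate_entropy(x),
                 apen_bruteforce(x), tolerance = 1e-10, label = nm)
  }
  # the alternating series is almost perfectly regular
  expect_lt(approximate_entropy(cases$alternating), 0.05)

  # both template-count conventions at m + 1 agree with the oracle's
  # denominator variants
  x <- cases$gaussian128
  r <- 0.1 * sd(x)
  a1 <- approximate_entropy(x, phi_m1_count = "n_minus_m_plus_1")
  a0 <- approximate_entropy(x, phi_m1_count = "n_minus_m")
  expect_equal(a1 - a0, log((length(x) - 1) / (length(x) - 2)),
               tolerance = 1e-9)
})

test_that("constant segments give exactly zero entropy", {
  for (n in c(32, 100, 512)) {
    expect_identical(approximate_entropy(rep(3.2, n)), 0)
  }
})

test_that("entropy orders constant < periodic < white noise", {
  wins <- 0L
  for (s in 1:50) {
    set.seed(s)
    n <- 256
    periodic <- sin(2 * pi * 8 * (1:n) / n)
    noise <- rnorm(n)
    a_per <- approximate_entropy(periodic)
    a_noise <- approximate_entropy(noise)
    expect_gte(a_per, 0)
    if (a_per < a_noise) wins <- wins + 1L
  }
  expect_gte(wins, 48)
})

test_that("entropy is invariant to positive amplitude scaling", {
  set.seed(42)
  x <- rnorm(300)
  # power-of-two scaling is exact in floating point
  expect_identical(approximate_entropy(x), approximate_entropy(4 * x))
  expect_equal(approximate_entropy(x), approximate_entropy(3.7 * x),
               tolerance = 1e-8)
})

test_that("entropy rejects too-short input and handles missing neighbours", {
  expect_error(approximate_entropy(c(1, 2, 3), m = 2),
               class = "pcgbeam_input_error")
  # without self-matches an isolated template leaves ApEn undefined
  set.seed(43)
  expect_warning(
    out <- approximate_entropy(rnorm(64), self_match = FALSE, r = 1e-12),
    "no neighbour")
  expect_true(is.na(out))
})

test_that("the power spectrum localizes bin-aligned tones and obeys Parseval", {
  t <- 0:511
  tone <- sin(2 * pi * 10 * t / 512)  # 78.125 Hz at 4 kHz
  sp <- power_spectrum(tone)
  expect_equal(sp$frequency[11], 78.125)
  expect_gt(sp$power[11] / sum(sp$power), 0.999)

  set.seed(44)
  x <- rnorm(512)
  sp2 <- power_spectrum(x)
  expect_equal(sum(sp2$power), mean(x^2), tolerance = 1e-10)

  # spectrum of white noise is flat on average
  set.seed(45)
  acc <- numeric(257)
  for (i in 1:400) acc <- acc + power_spectrum(rnorm(512))$power
  mid <- acc[2:256]
  expect_lt(max(abs(mid / mean(mid) - 1)), 0.2)
})

test_that("the band-energy ratio splits at 150 Hz inside the 65-500 Hz band", {
  t <- 0:511
  below <- sin(2 * pi * 10 * t / 512)   # 78.125 Hz
  above <- sin(2 * pi * 40 * t / 512)   # 312.5 Hz

  r_below <- band_energy_ratio(power_spectrum(below))
  expect_lt(r_below$ratio, 1e-6)

  r_above <- band_energy_ratio(power_spectrum(above))
  expect_gt(r_above$ratio, 1e6)

  # an exactly empty denominator is flagged and reported as +Inf
  sp_empty <- power_spectrum(above)
  sp_empty$power[sp_empty$frequency <= 150] <- 0
  r_empty <- band_energy_ratio(sp_empty)
  expect_true(r_empty$degenerate)
  expect_identical(r_empty$ratio, Inf)

  r_mix <- band_energy_ratio(power_spectrum(below + above))
  expect_equal(r_mix$ratio, 1.0, tolerance = 1e-6)

  # out-of-band energy is excluded entirely
  dc_tone <- below + 5  # DC is outside 65-500 Hz
  expect_equal(band_energy_ratio(power_spectrum(dc_tone))$ratio,
               r_below$ratio, tolerance = 1e-12)

  # a bin centred exactly on the split counts as "below"
  tone150 <- sin(2 * pi * 150 * (0:3999) / 4000)
  r150 <- band_energy_ratio(power_spectrum(tone150))
  expect_gt(r150$energy_below, r150$energy_above)
  expect_lt(r150$ratio, 1e-6)
})

test_that("adding energy above the split never decreases the ratio", {
  set.seed(46)
  t <- 0:511
  for (i in 1:20) {
    x <- rnorm(512)
    base <- band_energy_ratio(power_spectrum(x))$ratio
    k <- sample(21:63, 1)              # bins strictly above 150 Hz
    boosted <- x + runif(1, 0.5, 3) * sin(2 * pi * k * t / 512)
    expect_gte(band_energy_ratio(power_spectrum(boosted))$ratio, base)
  }
})

test_that("segment_features assembles one labelled row per segment", {
  seg <- make_segment(make_band_signal(512, band = c(200, 400), seed = 47L))
  row <- segment_features(seg)
  expect_identical(nrow(row), 1L)
  expect_identical(row$subject_id, "T01")
  expect_gt(row$ratio, 1)
  expect_gt(row$apen, 0)
  expect_equal(row$energy_below_150 + row$energy_above_150,
               sum(power_spectrum(seg)$power[
                 power_spectrum(seg)$frequency >= 65 &
                 power_spectrum(seg)$frequency <= 500]),
               tolerance = 1e-10)
})
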