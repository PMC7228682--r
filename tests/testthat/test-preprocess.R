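test_that("the envelope detector finds every S2 within 10 ms at 60 bpm", {
  rec <- make_test_recording("normal", heart_rate = 60, duration_s = 15,
                             noise_snr_db = 20, seed = 31L)
  bf <- delay_and_sum(rec, compute_delays(rec$geometry))
  det <- detect_s2(bf)
  truth <- rec$annotations$s2
  expect_equal(length(det$s2_times), length(truth))
  expect_lt(max(abs(det$s2_times - truth)), 0.010)
})

test_that("detected beat counts scale with heart rate", {
  counts <- vapply(c(60, 90), function(hr) {
    rec <- make_test_recording("normal", heart_rate = hr, duration_s = 15,
                               noise_snr_db = 20, seed = 32L)
    bf <- delay_and_sum(rec, compute_delays(rec$geometry))
    truth <- length(rec$annotations$s2)
    det <- length(detect_s2(bf)$s2_times)
    expect_equal(det, truth)
    det
  }, numeric(1))
  expect_gt(counts[2], counts[1] * 1.3)
})

test_that("a silent signal yields zero detections with a warning", {
  expect_warning(det <- detect_s2(numeric(4 * fs_pcg)), "no envelope peaks")
  expect_length(det$s2_times, 0)
})

test_that("diastolic windows cover [t + 0.100, t + 0.228) exactly", {
  x <- seq_len(20 * fs_pcg)  # ramp: sample value encodes its index
  # S2 at t = 1.000 s: 0-based samples 4400..4911 (1-based 4401..4912)
  segs <- extract_diastolic_segments(x, 1.0)
  expect_length(segs$segments, 1)
  s <- segs$segments[[1]]
  expect_identical(s$start_index, 4400)
  expect_length(s$samples, 512)
  expect_equal(s$samples, as.numeric(4401:4912))

  set.seed(33)
  for (t0 in runif(25, 0.5, 18)) {
    seg <- extract_diastolic_segments(x, t0)$segments[[1]]
    expect_identical(seg$start_index, round(t0 * fs_pcg) + 400)
    expect_length(seg$samples, 512)
  }
})

test_that("windows that overrun the record or collide with S1 are skipped", {
  x <- numeric(15 * fs_pcg)
  segs <- extract_diastolic_segments(x, c(5.0, 14.95))
  expect_length(segs$segments, 1)
  expect_identical(segs$skipped$reason, "window overruns record")

  # next S1 annotated 150 ms after S2: the 228-ms window must be dropped
  segs2 <- extract_diastolic_segments(x, 5.0, s1_times = c(4.5, 5.15))
  expect_length(segs2$segments, 0)
  expect_identical(segs2$skipped$reason, "window overlaps next S1")

  # kept + skipped partitions the S2 events
  rec <- make_test_recording("normal", heart_rate = 75, duration_s = 15,
                             noise_snr_db = Inf, seed = 34L)
  bf <- delay_and_sum(rec, compute_delays(rec$geometry))
  s2 <- detect_s2(bf, method = "ground_truth")
  segs3 <- extract_diastolic_segments(bf, s2)
  expect_identical(length(segs3$segments) + nrow(segs3$skipped),
                   length(s2$s2_times))
  # at 75 bpm the only losses are end-of-record windows, never S1 clashes
  expect_true(all(segs3$skipped$reason == "window overruns record"))
  in_record <- s2$s2_times[s2$s2_times + 0.228 <= 15]
  expect_identical(length(segs3$segments), length(in_record))
  expect_true(all(vapply(segs3$segments, function(s) length(s$samples),
                         integer(1)) == 512L))
})

test_that("normalization fixes unit mean energy, is idempotent and scale-free", {
  set.seed(35)
  x <- rnorm(512)
  seg <- make_segment(x)
  n1 <- normalize_segment(seg)
  expect_equal(mean(n1$samples^2), 1, tolerance = 1e-10)
  expect_true(n1$normalized)

  n2 <- normalize_segment(n1)
  expect_equal(n1$samples, n2$samples, tolerance = 1e-12)

  n7 <- normalize_segment(make_segment(7 * x))
  expect_equal(n1$samples, n7$samples, tolerance = 1e-12)

  # unit sine has mean square 1/2, so normalization doubles the energy:
  # amplitude becomes sqrt(2)
  tone <- sin(2 * pi * 10 * (0:511) / 512)  # bin-aligned
  expect_equal(max(abs(normalize_segment(tone))), sqrt(2), tolerance = 1e-9)

  expect_error(normalize_segment(numeric(512)),
               class = "pcgbeam_degenerate_input")
})

test_that("the 65-500 Hz Butterworth band-pass attenuates as designed", {
  t <- (0:7999) / fs_pcg
  mid <- 2001:6000
  gain_at <- function(freq) {
    tone <- sin(2 * pi * freq * t)
    out <- bandpass_segment(tone)
    sqrt(mean(out[mid]^2) / mean(tone[mid]^2))
  }
  expect_lt(20 * log10(gain_at(20)), -30)
  expect_gt(20 * log10(gain_at(200)), -1)

  # zero-phase mode leaves a passband tone unshifted: peak cross
  # correlation at lag 0
  tone <- sin(2 * pi * 200 * t)
  out <- bandpass_segment(tone)
  cc <- ccf(out[mid], tone[mid], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)

  expect_error(filter_spec(band = c(65, 2500)),
               class = "pcgbeam_config_error")
})

test_that("segment conditioning applies normalize-then-filter and records flags", {
  rec <- make_test_recording("pre_stent", heart_rate = 60, duration_s = 10,
                             noise_snr_db = 20, seed = 36L)
  bf <- delay_and_sum(rec, compute_delays(rec$geometry))
  segs <- extract_diastolic_segments(bf, detect_s2(bf, "ground_truth"))
  done <- condition_segments(segs)
  for (s in done$segments) {
    expect_true(s$normalized)
    expect_true(s$filtered)
    expect_length(s$samples, 512)
  }
})
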