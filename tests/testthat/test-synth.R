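test_that("generation is a pure function of the config seed", {
  cfg <- subject_config("pre_stent", seed = 7L,
                        cycle_template = cycle_template(timing_jitter_sd = 5))
  w1 <- generate_source_waveform(cfg)
  w2 <- generate_source_waveform(cfg)
  expect_identical(w1$samples, w2$samples)
  expect_identical(w1$annotations, w2$annotations)

  w3 <- generate_source_waveform(subject_config("pre_stent", seed = 8L,
    cycle_template = cycle_template(timing_jitter_sd = 5)))
  expect_false(identical(w1$samples, w3$samples))
})

test_that("normal subjects carry no murmur and no energy above 150 Hz in diastole", {
  cfg <- subject_config("normal", seed = 3L, duration_s = 10,
                        cycle_template = cycle_template(
                          heart_rate = 60, timing_jitter_sd = 0))
  w <- generate_source_waveform(cfg)
  expect_identical(nrow(w$annotations$murmur), 0L)
  expect_identical(w$config$murmur$gain, 0)

  # diastolic windows of the clean source: nothing but the low-frequency
  # background, so the 150-500 Hz share of energy is marginal
  segs <- extract_diastolic_segments(w$samples, w$annotations$s2)
  fracs <- vapply(segs$segments, function(s) {
    inband_energy_fraction(s$samples, c(150, 500), fs_pcg)
  }, numeric(1))
  expect_gt(length(fracs), 5)
  expect_lt(max(fracs), 0.05)
})

test_that("the isolated murmur component concentrates its energy in band", {
  tpl <- cycle_template(heart_rate = 60, timing_jitter_sd = 0)
  base <- list(cycle_template = tpl, duration_s = 10, seed = 11L)
  with_m <- generate_source_waveform(do.call(subject_config,
    c(list(condition = "pre_stent", murmur = murmur_model(gain = 0.2)), base)))
  without <- generate_source_waveform(do.call(subject_config,
    c(list(condition = "pre_stent", murmur = murmur_model(gain = 0)), base)))
  component <- with_m$samples - without$samples  # murmur drawn last
  expect_gt(sum(component^2), 0)
  expect_gte(inband_energy_fraction(component, c(150, 500), fs_pcg), 0.90)

  # murmur windows sit 100 ms after each S2 and inside the record
  mw <- with_m$annotations$murmur
  expect_equal(mw$onset, with_m$annotations$s2[seq_len(nrow(mw))] + 0.100,
               tolerance = 1e-9)
})

test_that("S1/S2/background components stay within their stated bands", {
  tpl <- cycle_template(heart_rate = 70, timing_jitter_sd = 0,
                        background_amplitude = 0)
  w_s1 <- generate_source_waveform(subject_config("normal",
    cycle_template(heart_rate = 70, timing_jitter_sd = 0,
                   background_amplitude = 0, s2_amplitude = 0),
    duration_s = 8, seed = 5L))
  expect_gte(inband_energy_fraction(w_s1$samples, tpl$s1_band, fs_pcg), 0.90)

  w_s2 <- generate_source_waveform(subject_config("normal",
    cycle_template(heart_rate = 70, timing_jitter_sd = 0,
                   background_amplitude = 0, s1_amplitude = 0),
    duration_s = 8, seed = 5L))
  expect_gte(inband_energy_fraction(w_s2$samples, tpl$s2_band, fs_pcg), 0.90)

  w_bg <- generate_source_waveform(subject_config("normal",
    cycle_template(heart_rate = 70, timing_jitter_sd = 0,
                   s1_amplitude = 0, s2_amplitude = 0),
    duration_s = 8, seed = 5L))
  expect_gte(inband_energy_fraction(w_bg$samples, tpl$background_band,
                                    fs_pcg), 0.99)
})

test_that("annotated S2 onsets align with the synthesized burst onsets", {
  cfg <- subject_config("normal",
    cycle_template(heart_rate = 60, timing_jitter_sd = 0,
                   background_amplitude = 0),
    duration_s = 8, seed = 2L)
  w <- generate_source_waveform(cfg)
  fs <- w$sample_rate
  for (ts2 in w$annotations$s2) {
    i0 <- round(ts2 * fs)           # 0-based onset sample
    pre <- w$samples[(i0 - 40):i0]  # 10 ms before onset: S1 long gone
    expect_equal(max(abs(pre)), 0)
    post <- w$samples[(i0 + 1):(i0 + 3)]  # Hann envelope ramps off zero
    expect_gt(max(abs(post)), 0)
  }
})

test_that("propagation applies exact geometric delays", {
  x <- make_band_signal(8000, seed = 4L)

  # equidistant elements: identical channels
  geom_eq <- source_geometry(source_position = c(0, 0, 0.05),
                             element_positions = rbind(c(0.01, 0, 0),
                                                       c(-0.01, 0, 0)))
  rec <- propagate_to_array(x, geom_eq)
  expect_equal(rec$samples[1, ], rec$samples[2, ], tolerance = 1e-10)

  # distances 60 and 75 mm at c = 1500 m/s: relative lag 1.0e-5 s
  rec2 <- propagate_to_array(x, line_geometry())
  lag <- phase_lag_seconds(rec2$samples[2, ], rec2$samples[1, ], fs_pcg)
  expect_equal(lag, 1.0e-5, tolerance = 0.02)

  # zero input propagates to zero
  rec0 <- propagate_to_array(numeric(8000), line_geometry())
  expect_equal(max(abs(rec0$samples)), 0)

  # source on an element is a geometry error
  expect_error(
    propagate_to_array(x, source_geometry(
      source_position = c(0.005, 0.005, 0))),
    class = "pcgbeam_geometry_error")
})

test_that("sensor noise hits its target power and is independent across channels", {
  n <- 60000
  x <- make_band_signal(n, seed = 9L)
  rec <- propagate_to_array(x, source_geometry())

  noisy <- add_sensor_noise(rec, snr_db = 0, seed = 21L)
  noise <- noisy$samples - rec$samples
  sig_pow <- rowMeans(rec$samples^2)
  noise_pow <- rowMeans(noise^2)
  expect_true(all(abs(noise_pow / sig_pow - 1) < 0.02))

  cors <- abs(cor(t(noise))[lower.tri(diag(4))])
  expect_lt(mean(cors), 0.02)

  # the +Inf sentinel disables noise entirely
  expect_identical(add_sensor_noise(rec, Inf)$samples, rec$samples)

  zero_rec <- multichannel_recording(matrix(0, 2, 100))
  expect_error(add_sensor_noise(zero_rec, 10),
               class = "pcgbeam_degenerate_input")
})

test_that("cohorts are labelled, paired and murmur-graded as constructed", {
  co <- generate_cohort(n_diseased = 3, n_normal = 1, master_seed = 55L,
                        duration_s = 10)
  expect_length(co$recordings, 7)
  expect_equal(as.integer(table(co$manifest$condition)[c("normal",
                                                         "post_stent",
                                                         "pre_stent")]),
               c(1L, 3L, 3L))

  # deterministic from the master seed
  co2 <- generate_cohort(n_diseased = 3, n_normal = 1, master_seed = 55L,
                         duration_s = 10)
  expect_identical(co$recordings[[1]]$samples, co2$recordings[[1]]$samples)

  for (pair in 1:3) {
    idx <- which(co$manifest$pair_id == pair)
    pre <- co$recordings[[idx[1]]]
    post <- co$recordings[[idx[2]]]
    expect_identical(pre$meta$condition, "pre_stent")
    expect_identical(post$meta$condition, "post_stent")
    # paired recordings share S1/S2 timing exactly
    expect_identical(pre$annotations$s1, post$annotations$s1)
    expect_identical(pre$annotations$s2, post$annotations$s2)

    # diastolic murmur band energy drops after stenting, in every pair
    band_e <- function(rec) {
      segs <- extract_diastolic_segments(rec$samples[1, ],
                                         rec$annotations$s2)
      mean(vapply(segs$segments, function(s) {
        e <- inband_energy_fraction(s$samples, c(150, 500), fs_pcg)
        e * mean(s$samples^2)
      }, numeric(1)))
    }
    expect_gt(band_e(pre), 2 * band_e(post))
  }
})

test_that("a contaminated (leaky-valve) subject keeps murmur energy after stenting", {
  band_e <- function(rec) {
    segs <- extract_diastolic_segments(rec$samples[1, ], rec$annotations$s2)
    mean(vapply(segs$segments, function(s) {
      inband_energy_fraction(s$samples, c(150, 500), fs_pcg) *
        mean(s$samples^2)
    }, numeric(1)))
  }
  clean <- generate_cohort(n_diseased = 2, n_normal = 0, master_seed = 88L,
                           duration_s = 10)
  leaky <- generate_cohort(n_diseased = 2, n_normal = 0, master_seed = 88L,
                           duration_s = 10, contaminated_subjects = 1L)
  post_of <- function(co, pair) {
    idx <- which(co$manifest$pair_id == pair &
                   co$manifest$condition == "post_stent")
    co$recordings[[idx]]
  }
  # the valve murmur persists post-stent for subject 1 only
  expect_gt(band_e(post_of(leaky, 1)), 5 * band_e(post_of(clean, 1)))
  expect_equal(band_e(post_of(leaky, 2)), band_e(post_of(clean, 2)),
               tolerance = 1e-10)
})
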