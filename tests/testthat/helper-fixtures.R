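# Shared fixture builders.  Everything is generated in code at test time.

fs_pcg <- 4000

# A compact subject recording (shorter than the study default) for unit
# tests that only need plausible structure, not the full 15 s.
make_test_recording <- function(condition = "normal", heart_rate = 60,
                                duration_s = 8, noise_snr_db = 20,
                                seed = 42L, timing_jitter_sd = 0,
                                murmur_gain = NULL,
                                geometry = source_geometry()) {
  tpl <- cycle_template(heart_rate = heart_rate,
                        timing_jitter_sd = timing_jitter_sd)
  mur <- if (is.null(murmur_gain)) murmur_model() else
    murmur_model(gain = murmur_gain)
  cfg <- subject_config(condition, tpl, mur, duration_s = duration_s,
                        noise_snr_db = noise_snr_db, seed = seed)
  rec <- propagate_to_array(generate_source_waveform(cfg), geometry)
  if (is.finite(noise_snr_db)) {
    rec <- add_sensor_noise(rec, noise_snr_db, seed = seed + 1L)
  }
  rec
}

# Band-limited test signal with unit RMS (stationary, no heart structure).
make_band_signal <- function(n, band = c(80, 400), seed = 1L) {
  set.seed(seed)
  w <- rnorm(n)
  wf <- fft(w)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs_pcg / n
  wf[!(f >= band[1] & f <= band[2])] <- 0 + 0i
  x <- Re(fft(wf, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Two-element line geometry with source-to-element distances d1, d2.
line_geometry <- function(d1 = 0.060, d2 = 0.075, c_sound = 1500) {
  source_geometry(source_position = c(0, 0, 0),
                  element_positions = rbind(c(d1, 0, 0), c(d2, 0, 0)),
                  propagation_speed = c_sound)
}

make_segment <- function(samples, fs = fs_pcg) {
  structure(list(samples = as.numeric(samples), sample_rate = fs,
                 s2_time = NA_real_, start_index = NA_integer_,
                 cycle_index = 1L, subject_id = "T01",
                 condition = "normal", normalized = FALSE,
                 filtered = FALSE),
            class = "pcg_segment")
}
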