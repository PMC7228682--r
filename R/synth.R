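# Synthetic phonocardiogram generation.
#
# The generator emulates the statistical structure that the downstream
# analysis assumes: quasi-periodic S1/S2 valve-closure bursts, a continuous
# low-frequency cardiohemic background, a diastolic turbulence murmur
# confined above 150 Hz for occluded (pre-stent) subjects, geometric
# propagation of the source to a small chest-surface microphone array, and
# additive white sensor noise.  Every output is a pure function of its
# configuration, including the seed.

PCG_SAMPLE_RATE <- 4000

#' Heart-cycle template for the synthetic generator
#'
#' Describes the deterministic skeleton of one cardiac cycle: S1 and S2
#' valve-closure bursts (band-limited noise under a Hann envelope) plus a
#' continuous low-frequency cardiohemic background present in diastole of
#' every subject.
#'
#' @param heart_rate Beats per minute.
#' @param s1_duration,s2_duration Burst durations, ms.
#' @param s1_band,s2_band Frequency bands of the bursts, Hz.
#' @param s1_amplitude,s2_amplitude Peak-envelope amplitudes, linear units.
#' @param systole_fraction Fraction of the cycle between S1 onset and S2
#'   onset.
#' @param timing_jitter_sd Cycle-to-cycle jitter of burst onsets, ms.
#' @param background_band Band of the continuous diastolic background, Hz.
#' @param background_amplitude RMS amplitude of the background, linear
#'   units (same scale as `s1_amplitude`).
#' @return An object of class `pcg_cycle_template`.
#' @export
cycle_template <- function(heart_rate = 70,
                           s1_duration = 100,
                           s2_duration = 80,
                           s1_band = c(30, 100),
                           s2_band = c(40, 150),
                           s1_amplitude = 1,
                           s2_amplitude = 0.8,
                           systole_fraction = 0.35,
                           timing_jitter_sd = 10,
                           background_band = c(20, 120),
                           background_amplitude = 0.08) {
  check_number(heart_rate, "heart_rate", lower = 20, upper = 240)
  check_number(s1_duration, "s1_duration", lower = 0, strict_lower = TRUE)
  check_number(s2_duration, "s2_duration", lower = 0, strict_lower = TRUE)
  check_band(s1_band, "s1_band")
  check_band(s2_band, "s2_band")
  check_band(background_band, "background_band")
  check_number(s1_amplitude, "s1_amplitude", lower = 0)
  check_number(s2_amplitude, "s2_amplitude", lower = 0)
  check_number(systole_fraction, "systole_fraction", lower = 0.1, upper = 0.6)
  check_number(timing_jitter_sd, "timing_jitter_sd", lower = 0)
  check_number(background_amplitude, "background_amplitude", lower = 0)
  cycle_ms <- 60000 / heart_rate
  if (s1_duration + s2_duration >= cycle_ms) {
    stop_pcg("pcgbeam_config_error",
             "S1 + S2 durations (%g ms) exceed the cycle length (%g ms)",
             s1_duration + s2_duration, cycle_ms)
  }
  structure(list(
    heart_rate = heart_rate,
    s1_duration = s1_duration, s2_duration = s2_duration,
    s1_band = s1_band, s2_band = s2_band,
    s1_amplitude = s1_amplitude, s2_amplitude = s2_amplitude,
    systole_fraction = systole_fraction,
    timing_jitter_sd = timing_jitter_sd,
    background_band = background_band,
    background_amplitude = background_amplitude
  ), class = "pcg_cycle_template")
}

#' Diastolic turbulence murmur model
#'
#' The murmur radiated by turbulent flow through a stenosed coronary artery
#' is modelled as stationary Gaussian noise band-passed above 150 Hz and
#' placed in the diastolic window of every cycle, where coronary flow is
#' maximal.  Severity (percent stenosis) maps monotonically to gain.
#'
#' @param band Murmur band, Hz.
#' @param onset_after_s2 Murmur onset relative to S2 onset, ms.
#' @param duration Murmur duration, ms.
#' @param gain RMS amplitude relative to `s2_amplitude`; 0 disables the
#'   murmur.  Defaults to the severity mapping when `NULL`.
#' @param severity Percent stenosis in (0, 100]; `gain` defaults to
#'   `0.1 * (severity / 75)^2`.
#' @return An object of class `pcg_murmur_model`.
#' @export
murmur_model <- function(band = c(150, 500),
                         onset_after_s2 = 100,
                         duration = 200,
                         gain = NULL,
                         severity = 75) {
  check_band(band, "band")
  check_number(onset_after_s2, "onset_after_s2", lower = 0)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(severity, "severity", lower = 0, upper = 100)
  if (is.null(gain)) gain <- 0.1 * (severity / 75)^2
  check_number(gain, "gain", lower = 0)
  structure(list(
    band = band, onset_after_s2 = onset_after_s2, duration = duration,
    gain = gain, severity = severity
  ), class = "pcg_murmur_model")
}

#' Configuration of one synthetic subject recording
#'
#' @param condition One of `"pre_stent"`, `"post_stent"`, `"normal"`.  A
#'   non-zero murmur gain is only admissible before stent placement.
#' @param cycle_template A [cycle_template()].
#' @param murmur A [murmur_model()]; ignored (gain forced to 0) unless
#'   `condition = "pre_stent"`.
#' @param duration_s Recording length, seconds.
#' @param noise_snr_db Per-channel sensor-noise SNR in dB; `Inf` disables
#'   noise.
#' @param post_stent_low_freq_boost Linear factor `>= 1` applied to the
#'   S1/S2 amplitudes after stent placement (restored contractility
#'   strengthens valve-closure sounds).
#' @param valve_murmur_gain RMS amplitude (relative to `s2_amplitude`) of a
#'   valve-regurgitation murmur unrelated to any stenosis: unlike the
#'   turbulence murmur it persists in every condition, emulating a
#'   confounding leaky-valve subject.  Default 0 (absent).
#' @param seed Integer seed controlling every random draw of the waveform.
#' @param timing_seed Optional separate seed for cycle timing jitter, so a
#'   pre/post pair recorded from the same subject can share beat timing
#'   while burst and background textures differ between sessions.  Defaults
#'   to `seed`.
#' @return An object of class `pcg_subject_config`.
#' @export
subject_config <- function(condition = c("pre_stent", "post_stent", "normal"),
                           cycle_template = pcgbeam::cycle_template(),
                           murmur = murmur_model(),
                           duration_s = 15,
                           noise_snr_db = 20,
                           post_stent_low_freq_boost = 1.15,
                           valve_murmur_gain = 0,
                           seed = 1L,
                           timing_seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(cycle_template, "pcg_cycle_template"),
            inherits(murmur, "pcg_murmur_model"))
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (!identical(noise_snr_db, Inf)) {
    check_number(noise_snr_db, "noise_snr_db")
  }
  check_number(post_stent_low_freq_boost, "post_stent_low_freq_boost",
               lower = 1)
  check_number(valve_murmur_gain, "valve_murmur_gain", lower = 0)
  if (condition != "pre_stent" && murmur$gain > 0) {
    murmur$gain <- 0
  }
  structure(list(
    condition = condition,
    cycle_template = cycle_template,
    murmur = murmur,
    duration_s = duration_s,
    noise_snr_db = noise_snr_db,
    post_stent_low_freq_boost = post_stent_low_freq_boost,
    valve_murmur_gain = valve_murmur_gain,
    seed = as.integer(seed),
    timing_seed = as.integer(if (is.null(timing_seed)) seed else timing_seed)
  ), class = "pcg_subject_config")
}

#' Array and source geometry
#'
#' Default geometry is a planar 2-by-2 microphone grid with 10-mm pitch on
#' the chest surface (z = 0) and an acoustic source 40 mm deep, offset
#' 15 mm laterally from the array axis.  Propagation speed defaults to the
#' approximate speed of sound in chest tissue.
#'
#' @param source_position Numeric 3-vector, metres.
#' @param element_positions Matrix with one row per array element (3
#'   columns, metres).
#' @param propagation_speed Metres per second.
#' @return An object of class `pcg_geometry`.
#' @export
source_geometry <- function(source_position = c(0.015, 0, 0.040),
                            element_positions = rbind(
                              c(-0.005, -0.005, 0),
                              c( 0.005, -0.005, 0),
                              c(-0.005,  0.005, 0),
                              c( 0.005,  0.005, 0)),
                            propagation_speed = 1500) {
  if (!is.numeric(source_position) || length(source_position) != 3L) {
    stop_pcg("pcgbeam_config_error", "`source_position` must be a 3-vector")
  }
  element_positions <- as.matrix(element_positions)
  if (ncol(element_positions) != 3L || nrow(element_positions) < 1L) {
    stop_pcg("pcgbeam_config_error",
             "`element_positions` must be an M x 3 matrix")
  }
  check_number(propagation_speed, "propagation_speed",
               lower = 0, strict_lower = TRUE)
  d <- element_distances(source_position, element_positions)
  if (any(d <= 0)) {
    stop_pcg("pcgbeam_geometry_error",
             "source position coincides with an array element")
  }
  structure(list(
    source_position = as.numeric(source_position),
    element_positions = element_positions,
    propagation_speed = propagation_speed
  ), class = "pcg_geometry")
}

element_distances <- function(source_position, element_positions) {
  sqrt(colSums((t(element_positions) - source_position)^2))
}

#' Construct a multichannel recording object
#'
#' @param samples Numeric matrix, one row per channel.
#' @param sample_rate Samples per second.
#' @param annotations Ground-truth event list with components `s1`, `s2`
#'   (onset times, seconds) and `murmur` (data frame with `onset`/`offset`),
#'   or `NULL`.
#' @param channel_map Integer vector mapping channel index to array-element
#'   index.
#' @param geometry Optional [source_geometry()] used to synthesize the
#'   recording.
#' @param meta Optional named list (subject id, condition label, ...).
#' @return An object of class `pcg_recording`.
#' @export
multichannel_recording <- function(samples, sample_rate = PCG_SAMPLE_RATE,
                                   annotations = NULL,
                                   channel_map = seq_len(nrow(samples)),
                                   geometry = NULL, meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (!is.null(annotations)) {
    for (ev in c("s1", "s2")) {
      tt <- annotations[[ev]]
      if (length(tt) > 1 && any(diff(tt) <= 0)) {
        stop_pcg("pcgbeam_config_error",
                 "%s annotations must be strictly increasing", ev)
      }
    }
  }
  structure(list(
    samples = samples, sample_rate = sample_rate,
    channel_map = as.integer(channel_map),
    annotations = annotations, geometry = geometry, meta = meta
  ), class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate))
  if (!is.null(x$meta$subject_id)) {
    cat(sprintf("  subject: %s  condition: %s\n",
                x$meta$subject_id, x$meta$condition %||% "?"))
  }
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %d S1, %d S2, %d murmur window(s)\n",
                length(x$annotations$s1), length(x$annotations$s2),
                NROW(x$annotations$murmur)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the mono acoustic source waveform for one subject
#'
#' Synthesizes `duration_s` seconds at 4 kHz containing, per cardiac cycle,
#' an S1 burst, an S2 burst and -- if and only if the murmur gain is
#' positive -- a diastolic turbulence-murmur burst starting
#' `onset_after_s2` ms after the S2 onset.  A continuous low-frequency
#' cardiohemic background runs under the whole record.  Exact S1/S2 onset
#' times and murmur windows are returned as annotations; onsets are snapped
#' to the sample grid so annotations align with burst onsets exactly.
#'
#' @param config A [subject_config()].
#' @return A list of class `pcg_waveform` with components `samples`,
#'   `sample_rate`, `annotations` and `config`.
#' @export
generate_source_waveform <- function(config) {
  stopifnot(inherits(config, "pcg_subject_config"))
  fs <- PCG_SAMPLE_RATE
  tpl <- config$cycle_template
  n <- round(config$duration_s * fs)
  if (n < 1) stop_pcg("pcgbeam_config_error", "nonpositive duration")
  cycle_s <- 60 / tpl$heart_rate
  ncyc <- floor((config$duration_s - 0.1) / cycle_s) + 1L

  boost <- if (config$condition == "post_stent") {
    config$post_stent_low_freq_boost
  } else 1
  s1_amp <- tpl$s1_amplitude * boost
  s2_amp <- tpl$s2_amplitude * boost

  # Beat timing is drawn from its own seed so paired pre/post recordings of
  # one subject can share cycle timing across sessions.
  jitter <- with_seed(config$timing_seed,
                      stats::rnorm(ncyc, 0, tpl$timing_jitter_sd / 1000))
  s1_onset <- pmax(0, 0.1 + (seq_len(ncyc) - 1) * cycle_s + jitter)
  s2_onset <- s1_onset + tpl$systole_fraction * cycle_s
  s1_idx <- round(s1_onset * fs)   # 0-based sample offsets
  s2_idx <- round(s2_onset * fs)

  nd_s1 <- round(tpl$s1_duration / 1000 * fs)
  nd_s2 <- round(tpl$s2_duration / 1000 * fs)
  mur <- config$murmur
  nd_mur <- round(mur$duration / 1000 * fs)
  mur_idx <- s2_idx + round(mur$onset_after_s2 / 1000 * fs)

  x <- numeric(n)
  place <- function(x, bank, idx, amp) {
    nd <- nrow(bank)
    for (j in seq_along(idx)) {
      i0 <- idx[j]
      if (i0 >= 0 && i0 + nd <= n) {
        sel <- (i0 + 1):(i0 + nd)
        x[sel] <- x[sel] + amp * bank[, j]
      }
    }
    x
  }

  with_seed(config$seed, {
    s1_bank <- burst_bank(ncyc, nd_s1, tpl$s1_band, fs)
    s2_bank <- burst_bank(ncyc, nd_s2, tpl$s2_band, fs)
    bg <- band_noise(n, tpl$background_band, fs)
    # valve-closure transients are bell-shaped; the turbulence murmur is
    # sustained through its window, hence the flat-topped envelope
    mur_bank <- if (mur$gain > 0) {
      burst_bank(ncyc, nd_mur, mur$band, fs, envelope = "tukey")
    } else NULL
    # regurgitation murmur of a leaky valve: same diastolic placement,
    # present regardless of stent state; drawn last so configs differing
    # only in this component share all other draws
    valve_bank <- if (config$valve_murmur_gain > 0) {
      burst_bank(ncyc, nd_mur, mur$band, fs, envelope = "tukey")
    } else NULL
  })

  x <- place(x, s1_bank, s1_idx, s1_amp)
  x <- place(x, s2_bank, s2_idx, s2_amp)
  x <- x + tpl$background_amplitude * bg
  if (!is.null(mur_bank)) {
    x <- place(x, mur_bank, mur_idx, mur$gain * tpl$s2_amplitude)
  }
  if (!is.null(valve_bank)) {
    x <- place(x, valve_bank, mur_idx,
               config$valve_murmur_gain * tpl$s2_amplitude)
  }

  keep_s1 <- s1_idx >= 0 & s1_idx + nd_s1 <= n
  keep_s2 <- s2_idx >= 0 & s2_idx + nd_s2 <= n
  keep_mur <- !is.null(mur_bank) & mur_idx + nd_mur <= n
  ann <- list(
    s1 = s1_idx[keep_s1] / fs,
    s2 = s2_idx[keep_s2] / fs,
    murmur = if (!is.null(mur_bank)) {
      data.frame(onset = mur_idx[keep_mur] / fs,
                 offset = (mur_idx[keep_mur] + nd_mur) / fs)
    } else {
      data.frame(onset = numeric(0), offset = numeric(0))
    }
  )
  structure(list(samples = x, sample_rate = fs, annotations = ann,
                 config = config),
            class = "pcg_waveform")
}

#' Propagate a source waveform to the microphone array
#'
#' Each channel is the source waveform delayed by its geometric travel time
#' `d_m / c`, applied as an exact band-limited fractional-sample delay.
#' Spherical-spreading attenuation (`1/d_m`) is off by default so that
#' delay-and-sum beamforming recovers exactly M times the source amplitude.
#'
#' @param waveform A `pcg_waveform` from [generate_source_waveform()], or a
#'   plain numeric vector.
#' @param geometry A [source_geometry()].
#' @param attenuate If `TRUE`, scale channel m by `1/d_m`.
#' @return A [multichannel_recording()] (noise-free).
#' @export
propagate_to_array <- function(waveform, geometry = source_geometry(),
                               attenuate = FALSE) {
  stopifnot(inherits(geometry, "pcg_geometry"))
  if (inherits(waveform, "pcg_waveform")) {
    x <- waveform$samples
    fs <- waveform$sample_rate
    ann <- waveform$annotations
    meta <- list(condition = waveform$config$condition)
  } else {
    x <- as.numeric(waveform)
    fs <- PCG_SAMPLE_RATE
    ann <- NULL
    meta <- list()
  }
  if (any(!is.finite(x))) {
    stop_pcg("pcgbeam_input_error", "source waveform must be finite")
  }
  d <- element_distances(geometry$source_position, geometry$element_positions)
  if (any(d <= 0)) {
    stop_pcg("pcgbeam_geometry_error",
             "source position coincides with an array element")
  }
  delays <- d / geometry$propagation_speed
  samples <- fractional_shift_multi(x, delays * fs)
  if (attenuate) samples <- samples / d
  multichannel_recording(samples, fs, annotations = ann,
                         geometry = geometry, meta = meta)
}

#' Add independent white sensor noise to every channel
#'
#' Gaussian noise is scaled per channel so that signal power over noise
#' power equals `10^(snr_db / 10)`.  The signal power defaults to each
#' channel's own mean square; supplying `reference_power` instead fixes the
#' noise floor externally -- e.g. for a paired pre/post session recorded
#' with the same hardware, where the sensor noise level must not track the
#' louder post-stent valve sounds.
#'
#' @param recording A [multichannel_recording()].
#' @param snr_db Target per-channel SNR in dB; `Inf` returns the input
#'   unchanged.
#' @param seed Integer seed for the noise draws.
#' @param reference_power Optional per-channel (or scalar) signal power used
#'   to scale the noise.
#' @return A [multichannel_recording()] with noise added.
#' @export
add_sensor_noise <- function(recording, snr_db, seed = 1L,
                             reference_power = NULL) {
  stopifnot(inherits(recording, "pcg_recording"))
  if (identical(snr_db, Inf)) return(recording)
  check_number(snr_db, "snr_db")
  p_sig <- if (is.null(reference_power)) {
    rowMeans(recording$samples^2)
  } else {
    rep_len(reference_power, nrow(recording$samples))
  }
  if (all(p_sig == 0)) {
    stop_pcg("pcgbeam_degenerate_input",
             "all-zero recording: noise scale undefined")
  }
  noise_sd <- sqrt(p_sig) * 10^(-snr_db / 20)
  nchan <- nrow(recording$samples)
  nsamp <- ncol(recording$samples)
  noise <- with_seed(seed,
    matrix(stats::rnorm(nchan * nsamp), nchan, nsamp)) * noise_sd
  recording$samples <- recording$samples + noise
  recording$meta$noise_snr_db <- snr_db
  recording
}

#' Generate a labelled synthetic study cohort
#'
#' Produces paired pre-stent/post-stent recordings for each diseased
#' subject (shared subject-level template and beat timing; the murmur is
#' removed and the low-frequency S1/S2 boost applied after stenting) plus
#' independent normal-subject recordings.  Within a pair the sensor-noise
#' power is anchored to the pre-stent signal level, modelling a fixed
#' hardware noise floor across the two sessions.  The whole cohort is a
#' deterministic function of `master_seed`.
#'
#' @param n_diseased Number of diseased subjects (each contributes a
#'   pre/post pair).
#' @param n_normal Number of normal subjects.
#' @param master_seed Integer master seed.
#' @param template Baseline [cycle_template()]; per-subject heart rates are
#'   drawn from `heart_rate_range`.
#' @param murmur Baseline [murmur_model()]; per-subject severities are drawn
#'   from `severity_range` unless `murmur_gain` pins the gain.
#' @param geometry A [source_geometry()] shared by all recordings.
#' @param duration_s,noise_snr_db,post_stent_low_freq_boost Passed to each
#'   [subject_config()].
#' @param murmur_gain If non-`NULL`, fixes the pre-stent murmur gain for
#'   every diseased subject (use 0 for a null cohort with no murmur
#'   anywhere).
#' @param heart_rate_range,severity_range Uniform sampling ranges for
#'   subject-level variation.
#' @param contaminated_subjects Indices of diseased subjects given a
#'   leaky-valve regurgitation murmur that persists after stenting (a
#'   known confounder pattern).  Empty by default.
#' @param valve_murmur_gain Gain of that valve murmur for contaminated
#'   subjects.
#' @return A list of class `pcg_cohort` with components `recordings` (list
#'   of [multichannel_recording()]) and `manifest` (data frame).
#' @export
generate_cohort <- function(n_diseased = 8, n_normal = 2, master_seed = 101L,
                            template = cycle_template(),
                            murmur = murmur_model(),
                            geometry = source_geometry(),
                            duration_s = 15, noise_snr_db = 20,
                            post_stent_low_freq_boost = 1.15,
                            murmur_gain = NULL,
                            heart_rate_range = c(55, 90),
                            severity_range = c(60, 95),
                            contaminated_subjects = integer(0),
                            valve_murmur_gain = 0.08) {
  if (n_diseased < 1) {
    stop_pcg("pcgbeam_config_error", "need at least one diseased subject")
  }
  draws <- with_seed(master_seed, list(
    hr_d = stats::runif(n_diseased, heart_rate_range[1], heart_rate_range[2]),
    sev = stats::runif(n_diseased, severity_range[1], severity_range[2]),
    hr_n = stats::runif(max(n_normal, 1), heart_rate_range[1],
                        heart_rate_range[2]),
    seeds = sample.int(.Machine$integer.max - 1L, 5L * n_diseased +
                         2L * max(n_normal, 0L) + 1L)
  ))
  seeds <- draws$seeds
  next_seed <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      seeds[i]
    }
  })

  recordings <- list()
  rows <- list()
  add_rec <- function(rec, subject, condition, pair) {
    rec$meta$subject_id <- subject
    rec$meta$condition <- condition
    rec$meta$pair_id <- pair
    recordings[[length(recordings) + 1L]] <<- rec
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject, condition = condition, pair_id = pair,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_diseased)) {
    tpl_i <- template
    tpl_i$heart_rate <- draws$hr_d[i]
    mur_i <- murmur
    mur_i$severity <- draws$sev[i]
    mur_i$gain <- if (is.null(murmur_gain)) {
      murmur$gain * (draws$sev[i] / 75)^2
    } else {
      murmur_gain
    }
    timing_seed <- next_seed()
    vgain <- if (i %in% contaminated_subjects) valve_murmur_gain else 0
    cfg_pre <- subject_config("pre_stent", tpl_i, mur_i,
                              duration_s = duration_s,
                              noise_snr_db = noise_snr_db,
                              post_stent_low_freq_boost =
                                post_stent_low_freq_boost,
                              valve_murmur_gain = vgain,
                              seed = next_seed(), timing_seed = timing_seed)
    cfg_post <- subject_config("post_stent", tpl_i, mur_i,
                               duration_s = duration_s,
                               noise_snr_db = noise_snr_db,
                               post_stent_low_freq_boost =
                                 post_stent_low_freq_boost,
                               valve_murmur_gain = vgain,
                               seed = next_seed(), timing_seed = timing_seed)
    pre_clean <- propagate_to_array(generate_source_waveform(cfg_pre),
                                    geometry)
    post_clean <- propagate_to_array(generate_source_waveform(cfg_post),
                                     geometry)
    ref_power <- rowMeans(pre_clean$samples^2)
    add_rec(add_sensor_noise(pre_clean, noise_snr_db, next_seed(),
                             reference_power = ref_power),
            sprintf("D%02d", i), "pre_stent", i)
    add_rec(add_sensor_noise(post_clean, noise_snr_db, next_seed(),
                             reference_power = ref_power),
            sprintf("D%02d", i), "post_stent", i)
  }

  for (i in seq_len(n_normal)) {
    tpl_i <- template
    tpl_i$heart_rate <- draws$hr_n[i]
    cfg <- subject_config("normal", tpl_i, murmur_model(gain = 0),
                          duration_s = duration_s,
                          noise_snr_db = noise_snr_db,
                          seed = next_seed())
    clean <- propagate_to_array(generate_source_waveform(cfg), geometry)
    add_rec(add_sensor_noise(clean, noise_snr_db, next_seed()),
            sprintf("N%02d", i), "normal", NA_integer_)
  }

  structure(list(recordings = recordings,
                 manifest = do.call(rbind, rows),
                 master_seed = master_seed),
            class = "pcg_cohort")
}

#' @export
print.pcg_cohort <- function(x, ...) {
  cat(sprintf("<pcg_cohort> %d recording(s), master seed %d\n",
              length(x$recordings), x$master_seed))
  print(table(x$manifest$condition))
  invisible(x)
}
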