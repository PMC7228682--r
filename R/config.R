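# Study configuration: one central object collecting every tunable of the
# pipeline, serializable to JSON or YAML without loss.

#' Study configuration
#'
#' Collects the defaults of the whole pipeline: cohort composition, array
#' geometry, segment rule (128 ms at 100 ms after S2), filter design
#' (65-500 Hz Butterworth of order 5), approximate-entropy parameters
#' (m = 2, r = 0.1 SD) and the 150-Hz split frequency.
#'
#' @param n_diseased,n_normal Cohort composition (diseased subjects are
#'   paired pre/post).
#' @param master_seed Master seed for cohort generation.
#' @param duration_s Recording length per subject, seconds.
#' @param noise_snr_db Sensor-noise SNR, dB.
#' @param post_stent_low_freq_boost S1/S2 amplitude factor after stenting.
#' @param murmur_gain `NULL` for the severity-mapped default; a number pins
#'   the pre-stent murmur gain (0 gives a null cohort).
#' @param geometry A [source_geometry()].
#' @param segment_offset_s,segment_length,segments_per_recording Diastolic
#'   window rule: start relative to S2 (s), length (samples), windows kept
#'   per recording.
#' @param filter_order,filter_band,filter_mode Band-pass design; see
#'   [filter_spec()].
#' @param filter_before_normalize Swap the normalize-then-filter order.
#' @param apen_m,apen_r_coefficient Approximate-entropy parameters.
#' @param split_hz Band-energy-ratio split frequency.
#' @param s2_method `"ground_truth"` (use generator annotations) or
#'   `"envelope_detector"`.
#' @param pooling `"per_segment"` (n = subjects x segments) or
#'   `"per_subject"` (subject means).
#' @return An object of class `pcg_study_config`.
#' @export
study_config <- function(n_diseased = 8, n_normal = 2, master_seed = 101L,
                         duration_s = 15, noise_snr_db = 20,
                         post_stent_low_freq_boost = 1.15,
                         murmur_gain = NULL,
                         geometry = source_geometry(),
                         segment_offset_s = 0.100,
                         segment_length = 512L,
                         segments_per_recording = 10L,
                         filter_order = 5, filter_band = c(65, 500),
                         filter_mode = "zero_phase",
                         filter_before_normalize = FALSE,
                         apen_m = 2L, apen_r_coefficient = 0.1,
                         split_hz = 150,
                         s2_method = c("ground_truth", "envelope_detector"),
                         pooling = c("per_segment", "per_subject")) {
  s2_method <- match.arg(s2_method)
  pooling <- match.arg(pooling)
  stopifnot(inherits(geometry, "pcg_geometry"))
  structure(list(
    cohort = list(n_diseased = n_diseased, n_normal = n_normal,
                  master_seed = as.integer(master_seed),
                  duration_s = duration_s, noise_snr_db = noise_snr_db,
                  post_stent_low_freq_boost = post_stent_low_freq_boost,
                  murmur_gain = murmur_gain),
    geometry = geometry,
    segment = list(offset_s = segment_offset_s,
                   length_samples = as.integer(segment_length),
                   per_recording = as.integer(segments_per_recording)),
    filter = list(order = filter_order, band = filter_band,
                  mode = filter_mode,
                  before_normalize = filter_before_normalize),
    apen = list(m = as.integer(apen_m),
                r_coefficient = apen_r_coefficient),
    split_hz = split_hz,
    s2_method = s2_method,
    pooling = pooling
  ), class = "pcg_study_config")
}

# Build the cohort a config describes.
cohort_from_config <- function(config) {
  stopifnot(inherits(config, "pcg_study_config"))
  co <- config$cohort
  generate_cohort(
    n_diseased = co$n_diseased, n_normal = co$n_normal,
    master_seed = co$master_seed, geometry = config$geometry,
    duration_s = co$duration_s, noise_snr_db = co$noise_snr_db,
    post_stent_low_freq_boost = co$post_stent_low_freq_boost,
    murmur_gain = co$murmur_gain
  )
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$geometry <- list(
    source_position = config$geometry$source_position,
    element_positions = apply(config$geometry$element_positions, 1,
                              identity, simplify = FALSE),
    propagation_speed = config$geometry$propagation_speed
  )
  out
}

config_from_list <- function(x) {
  geom <- source_geometry(
    source_position = as.numeric(x$geometry$source_position),
    element_positions = do.call(rbind, lapply(x$geometry$element_positions,
                                              as.numeric)),
    propagation_speed = x$geometry$propagation_speed
  )
  study_config(
    n_diseased = x$cohort$n_diseased, n_normal = x$cohort$n_normal,
    master_seed = x$cohort$master_seed, duration_s = x$cohort$duration_s,
    noise_snr_db = x$cohort$noise_snr_db,
    post_stent_low_freq_boost = x$cohort$post_stent_low_freq_boost,
    murmur_gain = x$cohort$murmur_gain,
    geometry = geom,
    segment_offset_s = x$segment$offset_s,
    segment_length = x$segment$length_samples,
    segments_per_recording = x$segment$per_recording,
    filter_order = x$filter$order, filter_band = as.numeric(x$filter$band),
    filter_mode = x$filter$mode,
    filter_before_normalize = isTRUE(x$filter$before_normalize),
    apen_m = x$apen$m, apen_r_coefficient = x$apen$r_coefficient,
    split_hz = x$split_hz, s2_method = x$s2_method, pooling = x$pooling
  )
}

#' Write a study configuration to JSON or YAML
#'
#' @param config A [study_config()].
#' @param path Output path; format chosen by extension (`.json`, `.yaml` or
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    stop_pcg("pcgbeam_io_error", "unsupported config extension: %s", path)
  }
  invisible(path)
}

#' Read a study configuration from JSON or YAML
#'
#' @param path File written by [write_study_config()].
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    stop_pcg("pcgbeam_io_error", "config file not found: %s", path)
  }
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop_pcg("pcgbeam_io_error", "unsupported config extension: %s", path)
  }
  config_from_list(x)
}
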