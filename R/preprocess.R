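# Diastolic-window preprocessing.
#
# Using the second heart sound as the time reference, 128-ms windows
# starting 100 ms after each S2 onset are isolated from the beamformed
# signal (512 samples at 4 kHz), normalized to unit mean energy, and
# band-pass filtered 65-500 Hz with an order-5 Butterworth filter.  The
# window placement avoids the trailing edge of S2 and the leading edge of
# the next S1, and coincides with maximal coronary flow.

#' Band-pass filter specification
#'
#' @param order Butterworth design order per band edge (the default 5
#'   yields a 10th-order band-pass transfer function, as in the usual
#'   `butter(5, band)` design).
#' @param band Pass band in Hz.
#' @param mode `"zero_phase"` (forward-backward filtering, no group delay)
#'   or `"causal"` (single pass).
#' @param sample_rate Samples per second.
#' @return An object of class `pcg_filter_spec`.
#' @export
filter_spec <- function(order = 5, band = c(65, 500),
                        mode = c("zero_phase", "causal"),
                        sample_rate = PCG_SAMPLE_RATE) {
  mode <- match.arg(mode)
  check_number(order, "order", lower = 1)
  check_band(band, "band", nyquist = sample_rate / 2)
  structure(list(order = order, band = band, mode = mode,
                 sample_rate = sample_rate),
            class = "pcg_filter_spec")
}

butter_coefs <- function(spec) {
  signal::butter(spec$order, spec$band / (spec$sample_rate / 2),
                 type = "pass")
}

# Zero-phase filtering with reflective padding to tame edge transients in
# short windows.
filtfilt_reflect <- function(bf, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * 32L)
  left <- 2 * x[1] - x[seq(padlen + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(padlen + 1):(padlen + n)]
}

#' Detect second-heart-sound onsets from a beamformed signal
#'
#' Computes a smoothed Shannon-energy envelope, picks peaks separated by a
#' plausible refractory interval, and disambiguates S1 from S2 by the
#' alternating inter-peak gap structure (S2 terminates the shorter,
#' systolic gap).  Each detected peak time is converted to an onset by
#' subtracting half the expected S2 duration.  For synthetic recordings
#' carrying ground-truth annotations, `method = "ground_truth"` bypasses
#' the detector.
#'
#' @param beamformed A `pcg_beamformed` signal (or numeric vector).
#' @param method `"envelope_detector"` or `"ground_truth"` (requires
#'   annotations on `beamformed`).
#' @param s2_duration_ms Expected S2 burst duration used to convert
#'   envelope peaks to onsets.
#' @param smooth_ms Envelope smoothing window, ms.
#' @param min_gap_s Minimum separation between retained peaks, seconds.
#' @param threshold Peak acceptance threshold as a fraction of the maximum
#'   envelope value.
#' @return A list of class `pcg_s2_annotations` with `s2_times` (seconds,
#'   ascending), `confidence` and `method`.  If no peaks clear the
#'   threshold an empty annotation set is returned with a warning.
#' @export
detect_s2 <- function(beamformed,
                      method = c("envelope_detector", "ground_truth"),
                      s2_duration_ms = 80, smooth_ms = 40,
                      min_gap_s = 0.18, threshold = 0.15) {
  method <- match.arg(method)
  x <- if (inherits(beamformed, "pcg_beamformed")) beamformed$samples else
    as.numeric(beamformed)
  fs <- if (inherits(beamformed, "pcg_beamformed")) beamformed$sample_rate else
    PCG_SAMPLE_RATE

  if (method == "ground_truth") {
    ann <- beamformed$annotations
    if (is.null(ann) || is.null(ann$s2)) {
      stop_pcg("pcgbeam_input_error",
               "ground_truth method requires S2 annotations")
    }
    return(structure(list(s2_times = ann$s2,
                          confidence = rep(1, length(ann$s2)),
                          method = "ground_truth"),
                     class = "pcg_s2_annotations"))
  }
  if (length(x) < 2 * fs) {
    stop_pcg("pcgbeam_input_error", "signal shorter than 2 s")
  }

  empty <- function() {
    warning("no envelope peaks above threshold; returning empty annotations")
    structure(list(s2_times = numeric(0), confidence = numeric(0),
                   method = "envelope_detector"),
              class = "pcg_s2_annotations")
  }
  peak <- max(abs(x))
  if (peak == 0) return(empty())
  s <- x / peak
  e <- -s^2 * log(s^2 + .Machine$double.eps)
  w <- max(1L, round(smooth_ms / 1000 * fs))
  env <- stats::filter(e, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  thr <- threshold * max(env)
  gap <- round(min_gap_s * fs)
  cand <- which(env > thr)
  cand <- cand[cand > 1 & cand < length(env)]
  cand <- cand[env[cand] >= env[cand - 1] & env[cand] >= env[cand + 1]]
  if (!length(cand)) return(empty())
  # enforce the refractory gap, keeping the taller of clashing peaks
  ord <- cand[order(env[cand], decreasing = TRUE)]
  keep <- logical(0)
  for (p in ord) {
    if (!length(keep) || all(abs(keep - p) >= gap)) keep <- c(keep, p)
  }
  pk <- sort(keep)
  if (length(pk) < 3) return(empty())

  gaps <- diff(pk) / fs
  thr_gap <- mean(range(gaps))
  is_short <- gaps < thr_gap       # systolic gap: S1 -> S2
  s2_pk <- pk[which(is_short) + 1L]
  if (!length(s2_pk)) return(empty())
  onset <- s2_pk / fs - s2_duration_ms / 2000
  structure(list(s2_times = onset, confidence = env[s2_pk] / max(env),
                 method = "envelope_detector"),
            class = "pcg_s2_annotations")
}

#' Extract diastolic windows referenced to S2
#'
#' For each S2 onset at time `t`, emits the samples in
#' `[t + 0.100, t + 0.228)` seconds -- exactly 512 samples at 4 kHz.
#' Windows that would overrun the end of the record, or collide with the
#' next annotated S1 onset when annotations are available, are skipped with
#' a recorded reason.
#'
#' @param beamformed A `pcg_beamformed` signal (or numeric vector).
#' @param s2 A `pcg_s2_annotations` object or numeric vector of S2 onset
#'   times in seconds.
#' @param offset_s Window start relative to S2 onset (default 0.100 s).
#' @param length_samples Window length (default 512).
#' @param s1_times Optional next-S1 onset times used for collision checks;
#'   taken from `beamformed$annotations$s1` when present.
#' @param max_segments Keep at most this many valid windows (default all).
#' @return A list of class `pcg_segment_set`: `segments` (list of
#'   `pcg_segment`) and `skipped` (data frame of S2 times and reasons).
#' @export
extract_diastolic_segments <- function(beamformed, s2, offset_s = 0.100,
                                       length_samples = 512L,
                                       s1_times = NULL,
                                       max_segments = Inf) {
  x <- if (inherits(beamformed, "pcg_beamformed")) beamformed$samples else
    as.numeric(beamformed)
  fs <- if (inherits(beamformed, "pcg_beamformed")) beamformed$sample_rate else
    PCG_SAMPLE_RATE
  meta <- if (inherits(beamformed, "pcg_beamformed")) beamformed$meta else
    list()
  if (is.null(s1_times) && inherits(beamformed, "pcg_beamformed")) {
    s1_times <- beamformed$annotations$s1
  }
  s2_times <- if (inherits(s2, "pcg_s2_annotations")) s2$s2_times else
    as.numeric(s2)

  n <- length(x)
  segments <- list()
  skipped <- list()
  for (k in seq_along(s2_times)) {
    t0 <- s2_times[k]
    start0 <- round(t0 * fs) + round(offset_s * fs)  # 0-based first sample
    end0 <- start0 + length_samples - 1L
    reason <- NULL
    if (length(segments) >= max_segments) {
      reason <- "segment quota reached"
    } else if (start0 < 0 || end0 >= n) {
      reason <- "window overruns record"
    } else if (length(s1_times)) {
      nxt <- s1_times[s1_times > t0]
      if (length(nxt) && (end0 + 1) / fs > min(nxt)) {
        reason <- "window overlaps next S1"
      }
    }
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(s2_time = t0, reason = reason, stringsAsFactors = FALSE)
      next
    }
    seg <- structure(list(
      samples = x[(start0 + 1):(end0 + 1)],
      sample_rate = fs,
      s2_time = t0,
      start_index = start0,          # 0-based sample offset into the record
      cycle_index = k,
      subject_id = meta$subject_id %||% NA_character_,
      condition = meta$condition %||% NA_character_,
      normalized = FALSE, filtered = FALSE
    ), class = "pcg_segment")
    segments[[length(segments) + 1L]] <- seg
  }
  structure(list(
    segments = segments,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(s2_time = numeric(0), reason = character(0))
  ), class = "pcg_segment_set")
}

#' Normalize a segment to unit mean energy
#'
#' Divides the samples by the square root of their mean squared value, so
#' the mean energy of every segment is 1.  This removes inter-subject
#' attenuation differences (chest mass, sensor coupling) before spectral
#' and entropy analysis.  Idempotent and invariant to positive rescaling of
#' the input.
#'
#' @param segment A `pcg_segment` (or numeric vector).
#' @return The normalized segment (same class as input).
#' @export
normalize_segment <- function(segment) {
  x <- if (inherits(segment, "pcg_segment")) segment$samples else
    as.numeric(segment)
  ms <- mean(x^2)
  if (ms == 0) {
    stop_pcg("pcgbeam_degenerate_input", "all-zero segment cannot be normalized")
  }
  y <- x / sqrt(ms)
  if (inherits(segment, "pcg_segment")) {
    segment$samples <- y
    segment$normalized <- TRUE
    segment
  } else {
    y
  }
}

#' Band-pass filter a segment
#'
#' Applies the order-5 Butterworth band-pass (65-500 Hz by default).  In
#' the default zero-phase mode the filter runs forward and backward with
#' reflective padding, preserving waveform morphology inside the short
#' window.
#'
#' @param segment A `pcg_segment` (or numeric vector).
#' @param spec A [filter_spec()].
#' @return The filtered segment (same class as input).
#' @export
bandpass_segment <- function(segment, spec = filter_spec()) {
  stopifnot(inherits(spec, "pcg_filter_spec"))
  x <- if (inherits(segment, "pcg_segment")) segment$samples else
    as.numeric(segment)
  bf <- butter_coefs(spec)
  y <- if (spec$mode == "zero_phase") {
    filtfilt_reflect(bf, x)
  } else {
    as.numeric(signal::filter(bf, x))
  }
  if (inherits(segment, "pcg_segment")) {
    segment$samples <- y
    segment$filtered <- TRUE
    segment
  } else {
    y
  }
}

#' Condition a segment set for feature extraction
#'
#' Applies the standard processing order -- normalize to unit mean energy,
#' then band-pass filter -- to every segment.  `swap_order = TRUE` filters
#' first and normalizes afterwards (normalization then uses the post-filter
#' energy), for sensitivity checks.
#'
#' @param segment_set A `pcg_segment_set` from
#'   [extract_diastolic_segments()].
#' @param spec A [filter_spec()].
#' @param swap_order Filter before normalizing.
#' @return The conditioned `pcg_segment_set`.
#' @export
condition_segments <- function(segment_set, spec = filter_spec(),
                               swap_order = FALSE) {
  stopifnot(inherits(segment_set, "pcg_segment_set"))
  segment_set$segments <- lapply(segment_set$segments, function(seg) {
    if (swap_order) {
      normalize_segment(bandpass_segment(seg, spec))
    } else {
      bandpass_segment(normalize_segment(seg), spec)
    }
  })
  segment_set
}
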