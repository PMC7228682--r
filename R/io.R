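# Recording I/O: multichannel RIFF/WAVE files (float32 by default, PCM16
# supported on read and write) with ground-truth annotations in a sidecar
# CSV (columns: event_type, time_s, channel; channel = -1 marks source
# events not tied to one microphone).

#' Write a multichannel recording as a WAV file
#'
#' Samples are stored interleaved, 32-bit IEEE float by default so the
#' synthetic fixtures round-trip without quantization.  When the recording
#' carries annotations they are written to `<path>.events.csv` alongside.
#'
#' @param recording A [multichannel_recording()].
#' @param path Output `.wav` path.
#' @param format `"float32"` or `"pcm16"`.
#' @param sidecar Write the annotation sidecar when annotations exist.
#' @return `path`, invisibly.
#' @export
write_recording_wav <- function(recording, path, format = c("float32",
                                                            "pcm16"),
                                sidecar = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "pcg_recording"))
  nchan <- nrow(recording$samples)
  nsamp <- ncol(recording$samples)
  fs <- as.integer(round(recording$sample_rate))
  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  block_align <- nchan * bits %/% 8L
  data_bytes <- nsamp * block_align

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nchan, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  interleaved <- as.numeric(recording$samples)  # column-major = interleaved
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767,
                                          round(interleaved * 32767)))),
             con, size = 2, endian = "little")
  }
  if (sidecar && !is.null(recording$annotations)) {
    write_annotations(recording$annotations, sidecar_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".events.csv")

#' Read a multichannel WAV file
#'
#' Supports PCM16 and IEEE-float data.  If the file's rate differs from
#' 4000 Hz the signal is resampled (with a message); an annotation sidecar
#' written by [write_recording_wav()] is attached when present.
#'
#' @param path Input `.wav` path.
#' @param target_rate Resample target, Hz (`NULL` keeps the file rate).
#' @return A [multichannel_recording()].
#' @export
read_recording_wav <- function(path, target_rate = PCG_SAMPLE_RATE) {
  if (!file.exists(path)) {
    stop_pcg("pcgbeam_io_error", "file not found: %s", path)
  }
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) {
    stop_pcg("pcgbeam_io_error", "not a WAV file (too short): %s", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) {
    stop_pcg("pcgbeam_io_error", "missing RIFF header: %s", path)
  }
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) {
    stop_pcg("pcgbeam_io_error", "missing WAVE header: %s", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little")
      )
      if (len > 16) readBin(con, raw(), len - 16L)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), len)
    } else {
      readBin(con, raw(), len + len %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || fmt$channels < 1) {
    stop_pcg("pcgbeam_io_error", "unreadable or empty WAV file: %s", path)
  }
  samples <- if (fmt$code == 3L && fmt$bits == 32L) {
    readBin(data_raw, numeric(), n = length(data_raw) %/% 4L, size = 4,
            endian = "little")
  } else if (fmt$code == 1L && fmt$bits == 16L) {
    readBin(data_raw, integer(), n = length(data_raw) %/% 2L, size = 2,
            signed = TRUE, endian = "little") / 32767
  } else {
    stop_pcg("pcgbeam_io_error",
             "unsupported WAV encoding (format %d, %d bits)",
             fmt$code, fmt$bits)
  }
  mat <- matrix(samples, nrow = fmt$channels)
  rate <- fmt$rate
  if (!is.null(target_rate) && rate != target_rate) {
    message(sprintf("resampling %s from %d Hz to %d Hz", basename(path),
                    rate, target_rate))
    frac <- gcd_pair(target_rate, rate)
    mat <- t(apply(mat, 1, function(ch) {
      signal::resample(ch, target_rate / frac, rate / frac)
    }))
    rate <- target_rate
  }
  ann <- if (file.exists(sidecar_path(path))) {
    read_annotations(sidecar_path(path))
  } else {
    NULL
  }
  multichannel_recording(mat, rate, annotations = ann)
}

gcd_pair <- function(a, b) if (b == 0) a else gcd_pair(b, a %% b)

#' Write ground-truth annotations as CSV
#'
#' @param annotations Annotation list (`s1`, `s2`, `murmur`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- rbind(
    if (length(annotations$s1)) {
      data.frame(event_type = "s1", time_s = annotations$s1, channel = -1L)
    },
    if (length(annotations$s2)) {
      data.frame(event_type = "s2", time_s = annotations$s2, channel = -1L)
    },
    if (NROW(annotations$murmur)) {
      rbind(
        data.frame(event_type = "murmur_on",
                   time_s = annotations$murmur$onset, channel = -1L),
        data.frame(event_type = "murmur_off",
                   time_s = annotations$murmur$offset, channel = -1L)
      )
    }
  )
  if (is.null(df)) {
    df <- data.frame(event_type = character(0), time_s = numeric(0),
                     channel = integer(0))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an annotation sidecar CSV
#'
#' @param path CSV written by [write_annotations()].
#' @return Annotation list with `s1`, `s2` and `murmur` components.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  on_t <- sort(df$time_s[df$event_type == "murmur_on"])
  off_t <- sort(df$time_s[df$event_type == "murmur_off"])
  list(
    s1 = sort(df$time_s[df$event_type == "s1"]),
    s2 = sort(df$time_s[df$event_type == "s2"]),
    murmur = data.frame(onset = on_t,
                        offset = off_t[seq_along(on_t)])
  )
}

#' Write a per-segment feature table as CSV
#'
#' @param features Data frame from [run_study()] (`$features`) or built
#'   from [segment_features()] rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
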