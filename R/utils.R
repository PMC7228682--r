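# Internal helpers shared across modules.

# Raise a classed condition so callers can distinguish error families.
stop_pcg <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "pcgbeam_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_pcg("pcgbeam_config_error", "`%s` must be a single finite number", name)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop_pcg("pcgbeam_config_error", "`%s` = %g is out of range", name, x)
  }
  invisible(x)
}

check_band <- function(band, name, nyquist = 2000) {
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band))) {
    stop_pcg("pcgbeam_config_error", "`%s` must be two finite numbers", name)
  }
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyquist) {
    stop_pcg("pcgbeam_config_error",
             "`%s` = [%g, %g] must satisfy 0 < low < high < %g Hz",
             name, band[1], band[2], nyquist)
  }
  invisible(band)
}

rms <- function(x) sqrt(mean(x^2))
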