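#' Construct a waveform object
#'
#' A `waveform` is the package's in-memory representation of a mono audio
#' signal: a numeric sample vector plus its sample rate and the bit depth it
#' was (or will be) stored at. Samples are dimensionless acoustic pressure on
#' a nominal \[-1, 1\] scale.
#'
#' @param samples Numeric vector of finite sample values.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param bit_depth Integer bit depth (16 or 32) or `"continuous"` for an
#'   unquantized signal that has not passed through a device profile.
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration_s(w)
#' @export
waveform <- function(samples, sample_rate_hz, bit_depth = "continuous") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  if (!identical(bit_depth, "continuous") && !bit_depth %in% c(16, 32)) {
    stop("`bit_depth` must be 16, 32 or \"continuous\"", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = as.numeric(sample_rate_hz),
      bit_depth = bit_depth
    ),
    class = "waveform"
  )
}

#' @rdname waveform
#' @param x Object to test or print.
#' @export
is_waveform <- function(x) inherits(x, "waveform")

#' @rdname waveform
#' @param w A `waveform`.
#' @export
duration_s <- function(w) {
  stopifnot(is_waveform(w))
  length(w$samples) / w$sample_rate_hz
}

#' @rdname waveform
#' @param ... Ignored.
#' @export
print.waveform <- function(x, ...) {
  depth <- if (identical(x$bit_depth, "continuous")) "continuous" else {
    paste0(x$bit_depth, "-bit")
  }
  cat(sprintf(
    "<waveform: %d samples, %g Hz, %s, %.3f s, peak %.3f>\n",
    length(x$samples), x$sample_rate_hz, depth,
    duration_s(x), max(abs(x$samples))
  ))
  invisible(x)
}

#' Time axis of a waveform
#'
#' @param w A `waveform`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
wave_times <- function(w) {
  stopifnot(is_waveform(w))
  (seq_along(w$samples) - 1) / w$sample_rate_hz
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All stochastic generators in the package funnel
# through this so results are reproducible and order-independent.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a per-recording substream seed from a master seed and an index, kept
# below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647
}
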