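#' Band-pass filter specification
#'
#' The default chain applied to every recording before detection: a 6th-order
#' Butterworth high-pass at 100 Hz (suppresses heart sounds and handling
#' rumble) followed by a 4th-order Butterworth low-pass at 1000 Hz (suppresses
#' ambient hiss above the adventitious-sound band). Both stages are run
#' zero-phase (forward-backward), so the effective magnitude response is the
#' square of the single-pass response and crackle timing is not skewed.
#'
#' @param highpass_cutoff_hz,highpass_order High-pass corner and order.
#' @param lowpass_cutoff_hz,lowpass_order Low-pass corner and order.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(highpass_cutoff_hz = 100, highpass_order = 6,
                        lowpass_cutoff_hz = 1000, lowpass_order = 4) {
  stopifnot(highpass_cutoff_hz < lowpass_cutoff_hz,
            highpass_order >= 1, lowpass_order >= 1)
  structure(
    list(
      highpass_cutoff_hz = highpass_cutoff_hz,
      highpass_order = as.integer(highpass_order),
      lowpass_cutoff_hz = lowpass_cutoff_hz,
      lowpass_order = as.integer(lowpass_order),
      design_family = "Butterworth"
    ),
    class = "filter_spec"
  )
}

# Butterworth design as a cascade of second-order sections: prototype analog
# pole pairs, low-pass/high-pass frequency transform with pre-warped cutoff,
# bilinear transform per section. A direct-form realization of a 6th-order
# filter at 100 Hz / 44100 Hz concentrates roots near z = 1 and is fragile;
# biquads keep each stage well-conditioned.
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  wc <- 2 * fs * tan(pi * cutoff_hz / fs) # pre-warped analog cutoff, rad/s
  K <- 2 * fs
  sections <- list()
  for (k in seq_len(order %/% 2)) {
    # analog biquad: denominator s^2 + 2 cos(theta) wc s + wc^2, with the
    # pole-pair angles shifted by half a slot for odd orders (which also
    # carry a real pole, handled below)
    theta <- pi * (2 * k - 1 + order %% 2) / (2 * order)
    a <- c(1, 2 * cos(theta) * wc, wc^2)
    b <- if (type == "low") c(0, 0, wc^2) else c(1, 0, 0)
    B0 <- b[1] * K^2 + b[2] * K + b[3]
    B1 <- 2 * b[3] - 2 * b[1] * K^2
    B2 <- b[1] * K^2 - b[2] * K + b[3]
    A0 <- a[1] * K^2 + a[2] * K + a[3]
    A1 <- 2 * a[3] - 2 * a[1] * K^2
    A2 <- a[1] * K^2 - a[2] * K + a[3]
    sections[[k]] <- list(b = c(B0, B1, B2) / A0, a = c(1, A1 / A0, A2 / A0))
  }
  if (order %% 2 == 1) {
    # genuine first-order digital section: embedding it in a biquad would put
    # a pole on the unit circle and defeat filtfilt
    A0 <- K + wc
    if (type == "low") b <- c(wc, wc) / A0 else b <- c(K, -K) / A0
    sections[[length(sections) + 1]] <- list(b = b, a = c(1, (wc - K) / A0))
  }
  sections
}

# Zero-phase application of an SOS cascade (forward-backward over a
# zero-padded copy, so the overall response is |H|^2 with zero phase).
sos_filtfilt <- function(sections, x) {
  m <- t(vapply(sections, function(s) {
    c(c(s$b, 0, 0)[1:3], c(s$a, 0, 0)[1:3])
  }, numeric(6)))
  sosfilt_cpp(m, x, TRUE, min(length(x) - 1L, 4096L))
}

#' Peak-normalize a waveform
#'
#' Rescales so the maximum absolute sample equals `target_peak` (default 0.9,
#' leaving headroom before 16-bit quantization). The signal shape is
#' unchanged: the output is the input times a positive scalar.
#'
#' @param w A [waveform()].
#' @param target_peak Target peak amplitude in (0, 1\].
#' @return A normalized [waveform()].
#' @export
normalize <- function(w, target_peak = 0.9) {
  stopifnot(is_waveform(w), target_peak > 0, target_peak <= 1)
  peak <- max(abs(w$samples))
  if (peak == 0) {
    stop("cannot normalize an all-zero waveform", call. = FALSE)
  }
  waveform(w$samples * (target_peak / peak), w$sample_rate_hz, "continuous")
}

#' Apply the Butterworth band-pass chain
#'
#' High-pass then low-pass, both zero-phase second-order-section Butterworth
#' cascades. Output length equals input length. If the sample rate is at or
#' below twice the low-pass cutoff the low-pass stage is unrealizable and is
#' skipped with a warning (the high-pass still runs); at 4000 Hz the default
#' 1000 Hz low-pass is still realizable since Nyquist is 2000 Hz.
#'
#' @param w A [waveform()].
#' @param spec A [filter_spec()].
#' @return The filtered [waveform()].
#' @export
bandpass <- function(w, spec = filter_spec()) {
  stopifnot(is_waveform(w), inherits(spec, "filter_spec"))
  fs <- w$sample_rate_hz
  if (fs <= 2 * spec$highpass_cutoff_hz) {
    stop("sample rate too low for the high-pass cutoff", call. = FALSE)
  }
  x <- sos_filtfilt(
    butter_sos(spec$highpass_order, spec$highpass_cutoff_hz, fs, "high"),
    w$samples
  )
  if (fs > 2 * spec$lowpass_cutoff_hz) {
    x <- sos_filtfilt(
      butter_sos(spec$lowpass_order, spec$lowpass_cutoff_hz, fs, "low"),
      x
    )
  } else {
    warning("sample rate ", fs, " Hz cannot realize the ",
            spec$lowpass_cutoff_hz, " Hz low-pass; stage skipped",
            call. = FALSE)
  }
  waveform(x, fs, "continuous")
}

#' Preprocess a recording
#'
#' The full conditioning chain applied before detection: peak normalization
#' followed by the band-pass of [bandpass()].
#'
#' @inheritParams bandpass
#' @param normalize_peak Target peak for [normalize()], or `NULL` to skip
#'   normalization.
#' @return A preprocessed [waveform()].
#' @export
preprocess <- function(w, spec = filter_spec(), normalize_peak = 0.9) {
  if (!is.null(normalize_peak)) w <- normalize(w, normalize_peak)
  bandpass(w, spec)
}
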