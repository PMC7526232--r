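#' Detector control parameters
#'
#' Tunable parameters of the rule-based detectors. The acceptance thresholds
#' themselves (`crackle_max_two_cycle_ms` 20, `crackle_max_total_ms` 25,
#' `wheeze_min_ms` 25, `wheeze_min_freq_hz` 100) are the a-priori
#' morphological criteria; everything else controls how candidates are
#' searched for.
#'
#' @param transient_k Envelope-to-rolling-median ratio above which a sample
#'   is a transient candidate.
#' @param median_window_ms Rolling-median window for the local envelope
#'   baseline. Must be several times the longest admissible crackle (25 ms),
#'   otherwise a transient inflates its own baseline and hides itself; the
#'   150 ms default is short enough to track the breath-cycle amplitude
#'   modulation (period ~3 s) and long enough that a crackle occupies a
#'   small minority of the window.
#' @param env_window_ms Short-time RMS window for the amplitude envelope.
#' @param frame_ms,hop_ms Spectrogram frame and hop lengths.
#' @param tonality_threshold Spectral peak-to-median magnitude ratio above
#'   which a frame counts as tonal. Both peak and median are taken over the
#'   analysis band only (`wheeze_min_freq_hz` to `wheeze_band_max_hz`): the
#'   band-passed signal has near-zero energy outside the band, and a
#'   full-axis median would make every frame look tonal.
#' @param freq_merge_tol Maximum relative change of peak frequency between
#'   consecutive tonal frames merged into one segment.
#' @param crackle_max_two_cycle_ms,crackle_max_total_ms Crackle acceptance
#'   criteria (strict upper bounds, ms).
#' @param wheeze_min_ms,wheeze_min_freq_hz Wheeze acceptance criteria
#'   (strict lower bounds, ms and Hz).
#' @param wheeze_band_max_hz Upper edge of the wheeze analysis band,
#'   matching the low-pass corner of the preprocessing chain.
#' @param crackle_score_scale Crackle count at which the saturating
#'   exponential score reaches 1 - 1/e.
#' @return A `detect_control` list.
#' @export
detect_control <- function(transient_k = 4, median_window_ms = 150,
                           env_window_ms = 2, frame_ms = 50, hop_ms = 12.5,
                           tonality_threshold = 6, freq_merge_tol = 0.2,
                           crackle_max_two_cycle_ms = 20,
                           crackle_max_total_ms = 25,
                           wheeze_min_ms = 25, wheeze_min_freq_hz = 100,
                           wheeze_band_max_hz = 1000,
                           crackle_score_scale = 4) {
  structure(as.list(environment()), class = "detect_control")
}

# Short-time RMS envelope via cumulative sums (O(n)); window centred.
rms_envelope <- function(x, fs, window_ms) {
  k <- max(3L, round(window_ms / 1000 * fs))
  if (k %% 2 == 0) k <- k + 1L
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Find transient candidates
#'
#' Candidate crackle windows: points where the short-time RMS envelope
#' exceeds `transient_k` times a rolling-median envelope baseline. Candidate
#' regions separated by less than 5 ms are merged; peaks closer than 20 ms
#' collapse onto the larger one, and the windows of surviving neighbours are
#' trimmed at the midpoint between peaks so candidates never overlap.
#'
#' @param w A preprocessed [waveform()].
#' @param control A [detect_control()].
#' @return A tibble with columns `peak_time_s`, `start_s`, `end_s`,
#'   `peak_amplitude`, one row per candidate window (about 55 ms wide).
#' @export
find_transients <- function(w, control = detect_control()) {
  stopifnot(is_waveform(w))
  fs <- w$sample_rate_hz
  env <- rms_envelope(w$samples, fs, control$env_window_ms)
  k_med <- max(3L, round(control$median_window_ms / 1000 * fs))
  if (k_med %% 2 == 0) k_med <- k_med + 1L
  # the baseline is smooth on the envelope timescale, so the rolling median
  # is computed on a decimated envelope and interpolated back
  dec <- max(1L, ceiling(k_med / 501))
  if (dec > 1L) {
    sub <- seq(1L, length(env), by = dec)
    k_sub <- max(3L, round(k_med / dec))
    if (k_sub %% 2 == 0) k_sub <- k_sub + 1L
    base_sub <- stats::runmed(env[sub], k_sub, endrule = "median")
    baseline <- stats::approx(sub, base_sub, xout = seq_along(env),
                              rule = 2)$y
  } else {
    baseline <- stats::runmed(env, k_med, endrule = "median")
  }
  hot <- env > control$transient_k * baseline & env > 1e-6
  empty <- tibble::tibble(peak_time_s = numeric(), start_s = numeric(),
                          end_s = numeric(), peak_amplitude = numeric())
  if (!any(hot)) return(empty)

  # contiguous hot regions, merging gaps under 5 ms
  r <- rle(hot)
  gap <- round(0.005 * fs)
  if (length(r$lengths) > 2) {
    short_gap <- !r$values & r$lengths < gap
    short_gap[1] <- FALSE; short_gap[length(short_gap)] <- FALSE
    r$values[short_gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- which(r$values)

  half_pre <- round(0.025 * fs)
  half_post <- round(0.030 * fs)
  cand <- lapply(regions, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    pk <- i0 - 1L + which.max(env[i0:i1])
    c(peak = pk, lo = max(1L, pk - half_pre),
      hi = min(length(env), pk + half_post), amp = env[pk])
  })
  cand <- do.call(rbind, cand)
  # resolve near-coincident excursions: peaks closer than 20 ms collapse to
  # the larger one; surviving neighbours keep distinct windows, trimmed at
  # the midpoint between adjacent peaks so windows never overlap
  min_sep <- round(0.020 * fs)
  cand <- cand[order(-cand[, "amp"]), , drop = FALSE]
  keep <- logical(nrow(cand))
  taken <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(abs(cand[i, "peak"] - taken) < min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i, "peak"])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand[, "peak"]), , drop = FALSE]
  if (nrow(cand) > 1) {
    for (i in seq_len(nrow(cand) - 1L)) {
      if (cand[i, "hi"] >= cand[i + 1L, "lo"]) {
        mid <- floor((cand[i, "peak"] + cand[i + 1L, "peak"]) / 2)
        cand[i, "hi"] <- mid
        cand[i + 1L, "lo"] <- mid + 1L
      }
    }
  }
  tibble::tibble(
    peak_time_s = (cand[, "peak"] - 1) / fs,
    start_s = (cand[, "lo"] - 1) / fs,
    end_s = (cand[, "hi"] - 1) / fs,
    peak_amplitude = cand[, "amp"]
  )
}

#' Validate a transient candidate against the crackle criteria
#'
#' Measures the candidate's waveform morphology and applies the a-priori
#' crackle definition. The transient onset is the last sub-10%-of-peak
#' envelope point before the envelope peak. The two-cycle duration runs from
#' onset to the fifth zero crossing after onset (the first crossing closes
#' the initial deflection; the next four complete two oscillation cycles).
#' The total duration runs from onset to the point where the amplitude
#' envelope decays to 10% of its peak; the envelope is sampled at the
#' per-half-cycle lobe maxima, the noise floor is removed in quadrature and
#' the 10% point is extrapolated from a log-linear fit of the decay (see
#' the source for the full rules). Acceptance requires
#' `measured_two_cycle_ms < 20` and `measured_total_ms < 25` (defaults).
#'
#' @param w The preprocessed [waveform()] the candidate came from.
#' @param candidate One row of the [find_transients()] tibble.
#' @param control A [detect_control()].
#' @return A one-row tibble with `peak_time_s`, `measured_two_cycle_ms`,
#'   `measured_total_ms`, `peak_amplitude`, `accepted`, `reason`.
#' @export
validate_crackle <- function(w, candidate, control = detect_control()) {
  fs <- w$sample_rate_hz
  i_lo <- max(1L, round(candidate$start_s * fs) + 1L)
  i_hi <- min(length(w$samples), round(candidate$end_s * fs) + 1L)
  x <- w$samples[i_lo:i_hi]
  env <- rms_envelope(x, fs, control$env_window_ms)
  # pin the working peak to the candidate's own excursion; the window may
  # graze a larger neighbouring transient
  pk_nominal <- round(candidate$peak_time_s * fs) + 1L - i_lo + 1L
  near <- max(1L, pk_nominal - round(0.005 * fs)):
    min(length(env), pk_nominal + round(0.005 * fs))
  pk <- near[which.max(env[near])]
  # duration threshold: 10% of the envelope peak, but never below the local
  # noise floor (lower-quartile envelope; the transient occupies well under
  # half the window) — a sub-floor threshold is never crossed and would run
  # the measured duration out to the window edges
  floor_est <- stats::quantile(env, 0.25, names = FALSE)
  thr <- max(0.1 * env[pk], 1.3 * floor_est)

  below_pre <- which(env[seq_len(pk)] < thr)
  onset <- if (length(below_pre)) max(below_pre) else 1L

  reject <- function(reason) tibble::tibble(
    peak_time_s = candidate$peak_time_s,
    measured_two_cycle_ms = NA_real_, measured_total_ms = NA_real_,
    peak_amplitude = candidate$peak_amplitude,
    accepted = FALSE, reason = reason
  )

  # zero crossings after onset
  xo <- x[onset:length(x)]
  sgn <- sign(xo); sgn[sgn == 0] <- 1
  crossings <- which(diff(sgn) != 0)
  if (length(crossings) < 5) return(reject("too few oscillations"))
  two_cycle_ms <- crossings[5] / fs * 1000

  # total duration: time until the amplitude envelope decays to 10% of its
  # peak. The envelope is sampled at the per-half-cycle lobe maxima (one
  # |x| maximum between consecutive zero crossings -- for a damped sinusoid
  # these lie exactly on the decay curve, and unlike a short-window RMS
  # envelope they do not oscillate when the window is shorter than the
  # period). After removing the noise floor in quadrature, the log-lobe
  # decay slope is fitted over the clean upper part of the tail (peak lobe
  # down to 30%) and the 10% point is extrapolated -- waiting for the noisy
  # envelope itself to cross 10% systematically overestimates the width,
  # and a non-decaying candidate (a sustained tone) extrapolates to an
  # effectively infinite width and is rejected.
  cr_all <- c(0L, crossings, length(xo))
  lobe_amp <- lobe_t <- numeric(length(cr_all) - 1L)
  for (j in seq_len(length(cr_all) - 1L)) {
    seg <- (cr_all[j] + 1L):cr_all[j + 1L]
    k <- seg[which.max(abs(xo[seg]))]
    lobe_amp[j] <- abs(xo[k])
    lobe_t[j] <- (k - 1L) / fs
  }
  amp_floor <- 1.3 * floor_est * sqrt(2) # RMS floor to amplitude scale
  lobe_c <- sqrt(pmax(lobe_amp^2 - amp_floor^2, 0))
  pk_lobe <- which.max(lobe_c)
  total_ms <- Inf
  if (lobe_c[pk_lobe] > 0) {
    run_end <- pk_lobe
    while (run_end < length(lobe_c) &&
           lobe_c[run_end + 1L] >= 0.3 * lobe_c[pk_lobe] &&
           lobe_c[run_end + 1L] <= 1.5 * lobe_c[run_end]) {
      run_end <- run_end + 1L
    }
    fit <- pk_lobe:run_end
    if (length(fit) >= 3) {
      ll <- log(lobe_c[fit])
      tt <- lobe_t[fit]
      slope <- stats::cov(tt, ll) / stats::var(tt)
      if (is.finite(slope) && slope < 0) {
        # lobe times are measured from onset, so this is the total width
        t10 <- lobe_t[pk_lobe] + log(0.1) / slope
        total_ms <- t10 * 1000
      }
    }
  }

  accepted <- two_cycle_ms < control$crackle_max_two_cycle_ms &&
    total_ms < control$crackle_max_total_ms
  tibble::tibble(
    peak_time_s = candidate$peak_time_s,
    measured_two_cycle_ms = two_cycle_ms,
    measured_total_ms = total_ms,
    peak_amplitude = candidate$peak_amplitude,
    accepted = accepted,
    reason = if (accepted) "" else "criteria not met"
  )
}

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed STFT via [signal::specgram()]. At a 4000 Hz input the
#' default 50 ms frame gives 200-sample frames and 20 Hz frequency
#' resolution.
#'
#' @param w A [waveform()].
#' @param frame_ms Frame length, >= 10 ms and no longer than the signal.
#' @param hop_ms Hop between frame starts.
#' @return A list of class `lung_spectrogram`: magnitude `mag`
#'   (frequency x time), bin frequencies `freq_hz`, frame-centre times
#'   `time_s`, and `frame_s`.
#' @export
spectrogram <- function(w, frame_ms = 50, hop_ms = 12.5) {
  stopifnot(is_waveform(w), frame_ms >= 10)
  fs <- w$sample_rate_hz
  n <- round(frame_ms / 1000 * fs)
  if (n > length(w$samples)) {
    stop("frame length exceeds the signal length", call. = FALSE)
  }
  hop <- max(1L, round(hop_ms / 1000 * fs))
  sg <- signal::specgram(w$samples, n = n, Fs = fs,
                         window = signal::hanning(n), overlap = n - hop)
  structure(
    list(mag = abs(sg$S), freq_hz = as.numeric(sg$f),
         time_s = as.numeric(sg$t), frame_s = n / fs),
    class = "lung_spectrogram"
  )
}

#' Find wheeze segments
#'
#' Applies the a-priori wheeze/rhonchi definition to a spectrogram. A frame
#' is tonal when its spectral peak magnitude exceeds `tonality_threshold`
#' times the frame's median magnitude and the peak frequency is above
#' `wheeze_min_freq_hz`. Runs of consecutive tonal frames whose peak
#' frequency changes by less than `freq_merge_tol` are merged; each run's
#' boundaries are then refined at sub-frame resolution from the envelope of
#' the signal band-passed around the run's dominant frequency (support above
#' half of the local envelope maximum). Segments longer than `wheeze_min_ms`
#' are returned.
#'
#' @param w The preprocessed [waveform()].
#' @param control A [detect_control()].
#' @return A tibble with columns `start_s`, `end_s`, `duration_ms`,
#'   `dominant_freq_hz`, `tonality`.
#' @export
find_wheeze_segments <- function(w, control = detect_control()) {
  stopifnot(is_waveform(w))
  fs <- w$sample_rate_hz
  S <- spectrogram(w, control$frame_ms, control$hop_ms)
  M <- S$mag
  nf <- ncol(M)
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_ms = numeric(),
                          dominant_freq_hz = numeric(), tonality = numeric())
  if (nf == 0) return(empty)

  band <- S$freq_hz > control$wheeze_min_freq_hz &
    S$freq_hz <= min(control$wheeze_band_max_hz, fs / 2)
  if (!any(band)) return(empty)
  Mb <- M[band, , drop = FALSE]
  band_freq <- S$freq_hz[band]
  peak_bin <- apply(Mb, 2, which.max)
  peak_freq <- band_freq[peak_bin]
  peak_mag <- Mb[cbind(peak_bin, seq_len(nf))]
  med_mag <- apply(Mb, 2, stats::median)
  ratio <- ifelse(med_mag > 0, peak_mag / med_mag, 0)
  tonal <- ratio > control$tonality_threshold &
    peak_freq > control$wheeze_min_freq_hz

  if (!any(tonal)) return(empty)

  # split tonal runs where the peak frequency jumps by more than the
  # tolerance between consecutive frames
  run_id <- integer(nf)
  current <- 0L
  for (j in seq_len(nf)) {
    if (!tonal[j]) next
    new_run <- current == 0L || !tonal[j - 1] ||
      abs(peak_freq[j] - peak_freq[j - 1]) >
        control$freq_merge_tol * peak_freq[j - 1]
    if (new_run) current <- current + 1L
    run_id[j] <- current
  }

  segs <- lapply(seq_len(max(run_id)), function(r) {
    j <- which(run_id == r)
    f0 <- stats::weighted.mean(peak_freq[j], peak_mag[j])
    t_lo <- max(0, min(S$time_s[j]) - S$frame_s / 2)
    t_hi <- min(duration_s(w), max(S$time_s[j]) + S$frame_s / 2)
    refined <- refine_tonal_support(w, t_lo, t_hi, f0)
    # re-estimate the dominant frequency on the refined slice with the full
    # periodogram: frame-level peaks are quantized to ~20 Hz bins, and for
    # an out-of-band tone the in-band frame peak sits on the high-pass
    # skirt rather than at the true frequency
    f_dom <- f0
    seg_tonal <- TRUE
    i1 <- floor(refined[1] * fs) + 1L
    i2 <- min(length(w$samples), ceiling(refined[2] * fs) + 1L)
    if (i2 - i1 + 1L >= 32L) {
      sl <- w$samples[i1:i2]
      nsl <- length(sl)
      mag <- Mod(stats::fft(sl * signal::hanning(nsl)))[seq_len(nsl %/% 2)]
      fr <- (seq_len(nsl %/% 2) - 1) * fs / nsl
      use <- fr > 20
      f_dom <- fr[use][which.max(mag[use])]
      # segment-level periodicity check: a wheeze concentrates its energy
      # at the dominant frequency, whereas a broadband transient (an onset
      # click of an out-of-band tone, a crackle cluster) spreads it and
      # fails the same peak-to-median ratio applied at segment scale
      in_band <- fr > control$wheeze_min_freq_hz &
        fr <= min(control$wheeze_band_max_hz, fs / 2)
      if (sum(in_band) >= 8) {
        med_band <- stats::median(mag[in_band])
        seg_tonal <- med_band > 0 &&
          max(mag[in_band]) / med_band > control$tonality_threshold
      }
    }
    tibble::tibble(
      start_s = refined[1], end_s = refined[2],
      duration_ms = (refined[2] - refined[1]) * 1000,
      dominant_freq_hz = f_dom,
      tonality = min(1, mean(ratio[j]) / (4 * control$tonality_threshold)),
      seg_tonal = seg_tonal
    )
  })
  segs <- dplyr::bind_rows(segs)
  segs <- dplyr::filter(segs, .data$duration_ms > control$wheeze_min_ms,
                        .data$dominant_freq_hz > control$wheeze_min_freq_hz,
                        .data$seg_tonal)
  dplyr::select(segs, -"seg_tonal")
}

# Sub-frame refinement of a tonal run: band-pass +-20% around the dominant
# frequency, subtract the noise floor (estimated from the slice margins,
# which lie outside the tonal frames) in quadrature, and take the stretch
# around the envelope maximum where the envelope stays above half its local
# maximum. Brief dips are bridged only between substantial lobes:
# simultaneous wheezes at nearby frequencies beat against each other and
# null the envelope every 1/|f1 - f2| seconds, which must not split one
# sustained segment — but the filter-ringing side lobes of a crackle
# transient must not be fused into a fake sustained segment either.
refine_tonal_support <- function(w, t_lo, t_hi, f0) {
  fs <- w$sample_rate_hz
  i_lo <- max(1L, floor(t_lo * fs) + 1L)
  i_hi <- min(length(w$samples), ceiling(t_hi * fs) + 1L)
  x <- w$samples[i_lo:i_hi]
  hi_cut <- min(1.2 * f0, 0.95 * fs / 2)
  x <- sos_filtfilt(butter_sos(2, 0.8 * f0, fs, "high"), x)
  x <- sos_filtfilt(butter_sos(2, hi_cut, fs, "low"), x)
  env <- rms_envelope(x, fs, 3)
  edge <- max(3L, round(0.020 * fs))
  floor_est <- min(stats::median(env[seq_len(min(edge, length(env)))]),
                   stats::median(env[seq.int(max(1L, length(env) - edge),
                                             length(env))]))
  env <- sqrt(pmax(env^2 - floor_est^2, 0))
  pk <- which.max(env)
  if (env[pk] <= 0) return(c((i_lo - 1L) / fs, (i_lo - 1L) / fs))
  above <- env >= 0.5 * env[pk]
  r <- rle(above)
  gap <- round(0.080 * fs)
  if (length(r$lengths) > 2) {
    dip <- !r$values & r$lengths < gap
    dip[1] <- FALSE; dip[length(dip)] <- FALSE
    if (any(dip)) {
      r$values[dip] <- TRUE
      above <- inverse.rle(r)
    }
  }
  lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk; while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
  c((i_lo - 1L + lo - 1L) / fs, (i_lo - 1L + hi - 1L) / fs)
}

#' Detect all events in a preprocessed recording
#'
#' Runs the wheeze segmentation first, then the crackle candidate/validation
#' chain on a tone-suppressed copy of the signal: over every detected wheeze
#' segment the narrow band around the segment's dominant frequency is
#' removed with a zero-phase band-stop (implemented as subtraction of the
#' band-passed component). A crackle riding on a loud wheeze is otherwise
#' buried — the sustained tone dominates the broadband envelope and its
#' rolling-median baseline — while the crackle itself is broadband and
#' survives the notch.
#'
#' @param w A preprocessed [waveform()].
#' @param control A [detect_control()].
#' @return A list with `crackles` (validated candidate tibble, accepted and
#'   rejected) and `wheezes` (segment tibble).
#' @export
detect_events <- function(w, control = detect_control()) {
  wheezes <- find_wheeze_segments(w, control)
  wq <- suppress_tones(w, wheezes)
  cands <- find_transients(wq, control)
  # candidates at wheeze-segment boundaries are discarded: the residual of
  # tone suppression is largest at the segment's onset/offset ramps, and
  # such an edge click (a brief decaying burst at the tone frequency) is
  # indistinguishable from a crackle
  if (nrow(cands) > 0 && nrow(wheezes) > 0) {
    edges <- c(wheezes$start_s, wheezes$end_s)
    at_edge <- vapply(cands$peak_time_s, function(t) {
      any(abs(t - edges) < 0.020)
    }, logical(1))
    cands <- cands[!at_edge, ]
  }
  crackles <- if (nrow(cands) == 0) {
    tibble::tibble(peak_time_s = numeric(), measured_two_cycle_ms = numeric(),
                   measured_total_ms = numeric(), peak_amplitude = numeric(),
                   accepted = logical(), reason = character())
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(cands)), function(i) {
      validate_crackle(wq, cands[i, ], control)
    }))
  }
  list(crackles = crackles, wheezes = wheezes)
}

# Remove the tonal component of each detected wheeze segment (fundamental
# plus harmonics) by complex demodulation: mix the slice down by the target
# frequency, low-pass the analytic amplitude/phase track (40 Hz corner, so
# onset/offset ramps and slow amplitude modulation are followed), remix and
# subtract. Unlike a band-stop filter this removes the tone with unit gain
# at its exact frequency while leaving broadband transients almost intact.
suppress_tones <- function(w, wheezes) {
  if (nrow(wheezes) == 0) return(w)
  fs <- w$sample_rate_hz
  x <- w$samples
  lp40 <- butter_sos(2, 40, fs, "low")
  for (i in seq_len(nrow(wheezes))) {
    f0 <- wheezes$dominant_freq_hz[i]
    i_lo <- max(1L, floor((wheezes$start_s[i] - 0.05) * fs) + 1L)
    i_hi <- min(length(x), ceiling((wheezes$end_s[i] + 0.05) * fs) + 1L)
    slice <- x[i_lo:i_hi]
    t <- (seq_along(slice) - 1) / fs
    for (h in 1:3) {
      fh <- h * f0
      if (fh >= 0.95 * fs / 2) break
      carrier <- exp(-2i * pi * fh * t)
      z <- slice * carrier
      zl <- complex(real = sos_filtfilt(lp40, Re(z)),
                    imaginary = sos_filtfilt(lp40, Im(z)))
      slice <- slice - 2 * Re(zl * Conj(carrier))
    }
    x[i_lo:i_hi] <- slice
  }
  waveform(x, fs, w$bit_depth)
}

#' Score a recording
#'
#' Maps detections to the per-recording continuous score pair (the
#' probability-raster analog): the crackle score is a saturating exponential
#' in the number of accepted crackles, `1 - exp(-n / scale)` with scale 4;
#' the wheeze score is the fraction of the recording covered by the union of
#' detected wheeze segments, capped at 1. Both scores are in \[0, 1\] and
#' monotone in detection count/coverage.
#'
#' @param w A preprocessed [waveform()].
#' @param control A [detect_control()].
#' @param detections Optional precomputed [detect_events()] result.
#' @return A one-row tibble with `crackle_score`, `wheeze_score`,
#'   `n_crackles`, `wheeze_seconds`.
#' @export
score_recording <- function(w, control = detect_control(), detections = NULL) {
  if (is.null(detections)) detections <- detect_events(w, control)
  n_crackles <- sum(detections$crackles$accepted)
  crackle_score <- 1 - exp(-n_crackles / control$crackle_score_scale)

  segs <- detections$wheezes
  wheeze_seconds <- if (nrow(segs) == 0) 0 else {
    iv <- segs[order(segs$start_s), c("start_s", "end_s")]
    total <- 0; cur_lo <- iv$start_s[1]; cur_hi <- iv$end_s[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start_s[i] <= cur_hi) {
        cur_hi <- max(cur_hi, iv$end_s[i])
      } else {
        total <- total + cur_hi - cur_lo
        cur_lo <- iv$start_s[i]; cur_hi <- iv$end_s[i]
      }
    }
    total + cur_hi - cur_lo
  }
  wheeze_score <- min(1, wheeze_seconds / duration_s(w))
  tibble::tibble(crackle_score = crackle_score, wheeze_score = wheeze_score,
                 n_crackles = n_crackles, wheeze_seconds = wheeze_seconds)
}

#' Threshold scores into presence labels
#'
#' Presence is declared when the score is strictly greater than the cutoff —
#' the "> 0.00" convention, under which a score of exactly 0 at cutoff 0 is
#' labelled absent.
#'
#' @param scores A data frame with `crackle_score` and `wheeze_score`
#'   columns.
#' @param crackle_cutoff,wheeze_cutoff Cutoffs in \[0, 1\].
#' @return `scores` with logical columns `crackle_present` and
#'   `wheeze_present` added.
#' @export
label_recording <- function(scores, crackle_cutoff = 0, wheeze_cutoff = 0) {
  stopifnot(crackle_cutoff >= 0, crackle_cutoff <= 1,
            wheeze_cutoff >= 0, wheeze_cutoff <= 1)
  dplyr::mutate(
    scores,
    crackle_present = .data$crackle_score > crackle_cutoff,
    wheeze_present = .data$wheeze_score > wheeze_cutoff
  )
}
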