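#' Built-in stethoscope device profiles
#'
#' Two fidelity profiles emulating the recording formats of the paired
#' digital stethoscopes: a high-fidelity device writing 32-bit IEEE-float
#' audio at 44100 Hz and a low-fidelity device writing 16-bit PCM at 4000 Hz.
#'
#' @return A tibble with columns `name`, `sample_rate_hz`, `bit_depth`.
#' @export
device_profiles <- function() {
  tibble::tibble(
    name = c("hifi", "lofi"),
    sample_rate_hz = c(44100, 4000),
    bit_depth = c(32L, 16L)
  )
}

#' @rdname device_profiles
#' @param name Profile name, `"hifi"` or `"lofi"`.
#' @export
device_profile <- function(name) {
  p <- dplyr::filter(device_profiles(), .data$name == .env$name)
  if (nrow(p) != 1L) stop("unknown device profile: ", name, call. = FALSE)
  as.list(p)
}

#' Crackle synthesis parameters
#'
#' A crackle is modelled as a brief unidirectional initial deflection (a
#' half-cosine pulse) followed by an exponentially damped sinusoid. The
#' two-cycle duration is fixed by the oscillation frequency
#' (`2000 / oscillation_freq_hz` ms), and the damping time constant is chosen
#' so the envelope falls to 10% of its peak at `total_duration_ms` after
#' transient onset.
#'
#' @param onset_s Onset time within the recording, seconds.
#' @param oscillation_freq_hz Oscillation frequency of the damped sinusoid.
#' @param total_duration_ms Width of the whole transient (onset to the point
#'   where the envelope decays below 10% of peak).
#' @param initial_deflection_fraction Width of the initial deflection as a
#'   fraction of the two-cycle duration, in (0, 1).
#' @param amplitude Peak amplitude of the oscillation, > 0.
#' @return A `crackle_params` list; `two_cycle_duration_ms` is derived.
#' @export
crackle_params <- function(onset_s = 0, oscillation_freq_hz = 300,
                           total_duration_ms = 20,
                           initial_deflection_fraction = 0.15,
                           amplitude = 1) {
  if (oscillation_freq_hz <= 0) stop("oscillation_freq_hz must be > 0", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (onset_s < 0) stop("onset_s must be >= 0", call. = FALSE)
  if (initial_deflection_fraction <= 0 || initial_deflection_fraction >= 1) {
    stop("initial_deflection_fraction must be in (0, 1)", call. = FALSE)
  }
  two_cycle <- 2000 / oscillation_freq_hz
  if (total_duration_ms <= two_cycle) {
    stop("total_duration_ms must exceed the two-cycle duration (",
         round(two_cycle, 2), " ms)", call. = FALSE)
  }
  structure(
    list(
      onset_s = onset_s,
      oscillation_freq_hz = oscillation_freq_hz,
      two_cycle_duration_ms = two_cycle,
      total_duration_ms = total_duration_ms,
      initial_deflection_fraction = initial_deflection_fraction,
      amplitude = amplitude
    ),
    class = "crackle_params"
  )
}

#' Wheeze synthesis parameters
#'
#' A wheeze is a sustained tonal segment: a sinusoid at the dominant
#' frequency plus optional weaker harmonics (each successive harmonic at 0.3
#' times the previous amplitude), with raised-cosine onset/offset ramps.
#'
#' @param onset_s Onset time within the recording, seconds.
#' @param dominant_freq_hz Fundamental frequency, Hz.
#' @param duration_ms Segment length, milliseconds.
#' @param amplitude Fundamental amplitude, > 0.
#' @param n_harmonics Number of harmonics above the fundamental (0 for a pure
#'   tone).
#' @return A `wheeze_params` list.
#' @export
wheeze_params <- function(onset_s = 0, dominant_freq_hz = 400,
                          duration_ms = 250, amplitude = 1,
                          n_harmonics = 0L) {
  if (dominant_freq_hz <= 0) stop("dominant_freq_hz must be > 0", call. = FALSE)
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (onset_s < 0) stop("onset_s must be >= 0", call. = FALSE)
  structure(
    list(
      onset_s = onset_s,
      dominant_freq_hz = dominant_freq_hz,
      duration_ms = duration_ms,
      amplitude = amplitude,
      n_harmonics = as.integer(n_harmonics)
    ),
    class = "wheeze_params"
  )
}

#' Acoustic ground-truth event
#'
#' Wraps crackle or wheeze parameters as an annotated event with explicit
#' kind and duration, the unit stored in truth-annotation files.
#'
#' @param params A [crackle_params()] or [wheeze_params()] object.
#' @return An `acoustic_event` list with `kind`, `onset_s`, `duration_s` and
#'   `params`.
#' @export
acoustic_event <- function(params) {
  kind <- if (inherits(params, "crackle_params")) "crackle"
  else if (inherits(params, "wheeze_params")) "wheeze"
  else stop("params must be crackle_params or wheeze_params", call. = FALSE)
  dur <- if (kind == "crackle") params$total_duration_ms / 1000
  else params$duration_ms / 1000
  structure(
    list(kind = kind, onset_s = params$onset_s, duration_s = dur,
         params = params),
    class = "acoustic_event"
  )
}

#' Synthesize a single crackle transient
#'
#' Renders the damped-sinusoid crackle model of [crackle_params()]: a
#' downward half-cosine deflection of width
#' `initial_deflection_fraction * two_cycle_duration`, then
#' `amplitude * exp(-t/tau) * sin(2 pi f t)` with `tau` set so the envelope
#' reaches 10% of peak at `total_duration_ms` after onset. The rendered
#' vector extends somewhat past the nominal total duration so that the decay
#' below 10% is observable.
#'
#' @param params A [crackle_params()].
#' @param sample_rate_hz Sampling rate; must be at least 4 times the
#'   oscillation frequency.
#' @return A [waveform()] holding just the transient (onset not applied).
#' @export
synth_crackle <- function(params, sample_rate_hz) {
  stopifnot(inherits(params, "crackle_params"))
  if (sample_rate_hz < 4 * params$oscillation_freq_hz) {
    stop("sample rate must be at least 4x the oscillation frequency",
         call. = FALSE)
  }
  f <- params$oscillation_freq_hz
  total_s <- params$total_duration_ms / 1000
  defl_s <- params$initial_deflection_fraction * params$two_cycle_duration_ms / 1000
  tau <- (total_s - defl_s) / log(10) # envelope hits 10% of peak at total_s
  n <- ceiling(1.3 * total_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- numeric(n)
  in_defl <- t < defl_s
  # downward half-cosine deflection, 60% of the oscillation amplitude
  x[in_defl] <- -0.6 * params$amplitude * sin(pi * t[in_defl] / defl_s)
  tp <- t[!in_defl] - defl_s
  x[!in_defl] <- params$amplitude * exp(-tp / tau) * sin(2 * pi * f * tp)
  waveform(x, sample_rate_hz)
}

#' Synthesize a wheeze segment
#'
#' Harmonic stack with 10 ms raised-cosine edge ramps (shorter for brief
#' segments). Harmonics at or above the Nyquist frequency are dropped.
#'
#' @param params A [wheeze_params()].
#' @param sample_rate_hz Sampling rate; the dominant frequency must be below
#'   Nyquist.
#' @return A [waveform()] of length `duration_ms` (onset not applied).
#' @export
synth_wheeze <- function(params, sample_rate_hz) {
  stopifnot(inherits(params, "wheeze_params"))
  if (params$dominant_freq_hz >= sample_rate_hz / 2) {
    stop("dominant frequency must be below the Nyquist frequency",
         call. = FALSE)
  }
  dur_s <- params$duration_ms / 1000
  n <- max(2L, round(dur_s * sample_rate_hz))
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- numeric(n)
  for (h in 0:params$n_harmonics) {
    fh <- params$dominant_freq_hz * (h + 1)
    if (fh >= sample_rate_hz / 2) break
    x <- x + params$amplitude * 0.3^h * sin(2 * pi * fh * t)
  }
  ramp_n <- min(round(0.010 * sample_rate_hz), floor(n / 4))
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
    x[(n - ramp_n + 1):n] <- x[(n - ramp_n + 1):n] * rev(ramp)
  }
  waveform(x, sample_rate_hz)
}

#' Synthesize vesicular breath-sound background
#'
#' Band-limited Gaussian noise (energy concentrated in 100-1000 Hz via a
#' zero-phase Butterworth band-pass) amplitude-modulated by a squared-sine
#' breath-cycle envelope with a small floor so the signal never vanishes
#' between breaths. Overall RMS is scaled to `rms`.
#'
#' @param duration_s Length in seconds.
#' @param cycle_period_s Breath cycle period (default 3 s, a typical
#'   pediatric respiratory rate of ~20 breaths/min).
#' @param sample_rate_hz Sampling rate.
#' @param seed Integer seed; identical seeds give identical waveforms.
#' @param rms Target root-mean-square amplitude.
#' @return A [waveform()].
#' @export
synth_breath_noise <- function(duration_s, cycle_period_s = 3,
                               sample_rate_hz = 44100, seed = 1, rms = 0.1) {
  stopifnot(duration_s > 0, cycle_period_s > 0)
  n <- round(duration_s * sample_rate_hz)
  x <- with_seed(seed, stats::rnorm(n))
  x <- sos_filtfilt(butter_sos(4, 100, sample_rate_hz, "high"), x)
  if (sample_rate_hz > 2000) {
    x <- sos_filtfilt(butter_sos(4, 1000, sample_rate_hz, "low"), x)
  }
  t <- (seq_len(n) - 1) / sample_rate_hz
  env <- 0.15 + 0.85 * sin(pi * t / cycle_period_s)^2
  x <- x * env
  waveform(x * (rms / sqrt(mean(x^2))), sample_rate_hz)
}

#' Mix ground-truth events into breath-sound background
#'
#' Adds each event to the background with a per-event gain chosen so the
#' event-to-noise power ratio over the event's support equals `snr_db`. If
#' the mix exceeds full scale it is rescaled globally (preserving all ratios)
#' to a peak of 0.99.
#'
#' @param events List of [acoustic_event()] objects; all must fit inside the
#'   recording.
#' @param duration_s Recording length, seconds.
#' @param sample_rate_hz Rendering rate.
#' @param snr_db Per-event signal-to-noise ratio in dB over the event
#'   support.
#' @param cycle_period_s,noise_rms Background parameters, see
#'   [synth_breath_noise()].
#' @param seed Integer seed for the background noise.
#' @return A list with elements `waveform` and `events` (the ground truth,
#'   passed through).
#' @export
render_recording <- function(events, duration_s = 20, sample_rate_hz = 44100,
                             snr_db = 20, cycle_period_s = 3,
                             noise_rms = 0.1, seed = 1) {
  noise <- synth_breath_noise(duration_s, cycle_period_s, sample_rate_hz,
                              seed = seed, rms = noise_rms)
  mix <- noise$samples
  for (ev in events) {
    stopifnot(inherits(ev, "acoustic_event"))
    if (ev$onset_s + ev$duration_s > duration_s) {
      stop("event at ", ev$onset_s, " s exceeds the recording duration",
           call. = FALSE)
    }
    ew <- if (ev$kind == "crackle") synth_crackle(ev$params, sample_rate_hz)
    else synth_wheeze(ev$params, sample_rate_hz)
    i0 <- round(ev$onset_s * sample_rate_hz) + 1
    idx <- i0:min(i0 + length(ew$samples) - 1, length(mix))
    e <- ew$samples[seq_along(idx)]
    p_noise <- mean(noise$samples[idx]^2)
    p_event <- mean(e^2)
    gain <- sqrt(p_noise * 10^(snr_db / 10) / p_event)
    mix[idx] <- mix[idx] + gain * e
  }
  peak <- max(abs(mix))
  if (peak > 1) mix <- mix * (0.99 / peak)
  list(waveform = waveform(mix, sample_rate_hz), events = events)
}

#' Degrade a waveform to a device profile
#'
#' Emulates what a given stethoscope stores: anti-aliased resampling to the
#' profile's sample rate (zero-phase 8th-order Butterworth at 90% of the new
#' Nyquist, then interpolation at the new sample times) followed by uniform
#' quantization to the profile's bit depth. Upsampling is refused — the
#' simulator always renders at the highest rate first.
#'
#' @param w A [waveform()].
#' @param profile A row of [device_profiles()] (as from [device_profile()]),
#'   or any list with `sample_rate_hz` and `bit_depth`.
#' @return A [waveform()] at the profile's rate and depth.
#' @export
apply_device_profile <- function(w, profile) {
  stopifnot(is_waveform(w))
  fs_out <- profile$sample_rate_hz
  if (fs_out > w$sample_rate_hz) {
    stop("device profile requests upsampling (", fs_out, " > ",
         w$sample_rate_hz, " Hz); render at the highest rate first",
         call. = FALSE)
  }
  x <- w$samples
  if (fs_out < w$sample_rate_hz) {
    x <- sos_filtfilt(butter_sos(8, 0.9 * fs_out / 2, w$sample_rate_hz, "low"), x)
    t_old <- (seq_along(x) - 1) / w$sample_rate_hz
    n_new <- floor(duration_s(w) * fs_out)
    t_new <- (seq_len(n_new) - 1) / fs_out
    x <- stats::approx(t_old, x, xout = t_new)$y
  }
  depth <- profile$bit_depth
  if (identical(depth, "continuous")) {
    return(waveform(x, fs_out, "continuous"))
  }
  if (depth == 16) {
    x <- pmin(pmax(round(x * 2^15), -2^15), 2^15 - 1) / 2^15
  }
  waveform(x, fs_out, as.integer(depth))
}

#' Default cohort configuration
#'
#' The study-shaped defaults: 25 participants in four groups (normal breath
#' sounds n = 9, wheeze only n = 5, crackles with or without wheeze n = 5,
#' cystic-fibrosis clinic attendees with a clear chest n = 6), four posterior
#' thorax quadrants each, recorded by both device profiles, 20-second
#' recordings, four aberrant recordings excluded per device, 7 of 25
#' participants female.
#'
#' @param group_sizes Named integer vector over the four groups.
#' @param quadrants Character vector of auscultation sites.
#' @param devices Device profile names, see [device_profiles()].
#' @param exclusions_per_device Number of aberrant recordings per device.
#' @param duration_s Recording length in seconds.
#' @param master_rate_hz Common rendering rate before device degradation.
#' @param snr_db Event-to-noise ratio of injected events.
#' @param crackle_rate,wheeze_rate Poisson means for events per 20-s
#'   recording in the groups that carry them.
#' @param wheeze_given_crackles Probability that a participant in the
#'   crackles group also wheezes.
#' @param cycle_period_s Breath cycle period, seconds.
#' @param n_female Number of female participants.
#' @param crackle_freq_range,wheeze_freq_range,wheeze_duration_range_ms
#'   Uniform draw ranges for event morphology parameters.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(normal = 9, wheeze_only = 5,
                                          crackles_pm_wheeze = 5, cf_clear = 6),
                          quadrants = c("left_upper", "right_upper",
                                        "left_lower", "right_lower"),
                          devices = c("hifi", "lofi"),
                          exclusions_per_device = 4,
                          duration_s = 20,
                          master_rate_hz = 44100,
                          snr_db = 20,
                          crackle_rate = 6,
                          wheeze_rate = 2,
                          wheeze_given_crackles = 0.5,
                          cycle_period_s = 3,
                          n_female = 7,
                          crackle_freq_range = c(150, 800),
                          wheeze_freq_range = c(150, 900),
                          wheeze_duration_range_ms = c(80, 2000)) {
  if (sum(group_sizes) < 1) stop("group sizes must sum to >= 1", call. = FALSE)
  groups <- c("normal", "wheeze_only", "crackles_pm_wheeze", "cf_clear")
  if (!all(names(group_sizes) %in% groups)) {
    stop("group_sizes names must be among: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      group_sizes = group_sizes, quadrants = quadrants, devices = devices,
      exclusions_per_device = exclusions_per_device, duration_s = duration_s,
      master_rate_hz = master_rate_hz, snr_db = snr_db,
      crackle_rate = crackle_rate, wheeze_rate = wheeze_rate,
      wheeze_given_crackles = wheeze_given_crackles,
      cycle_period_s = cycle_period_s, n_female = n_female,
      crackle_freq_range = crackle_freq_range,
      wheeze_freq_range = wheeze_freq_range,
      wheeze_duration_range_ms = wheeze_duration_range_ms
    ),
    class = "cohort_config"
  )
}

# Draw ground-truth events for one auscultation site. Crackle draws always
# satisfy 2CD < 20 ms and total < 25 ms; wheeze draws always satisfy
# duration > 25 ms and dominant frequency > 100 Hz.
draw_site_events <- function(group, wheezy_participant, config) {
  dur <- config$duration_s
  events <- list()
  if (group %in% c("normal", "cf_clear")) return(events)
  if (group == "crackles_pm_wheeze") {
    n_crackle <- stats::rpois(1, config$crackle_rate)
    for (i in seq_len(n_crackle)) {
      f <- stats::runif(1, config$crackle_freq_range[1], config$crackle_freq_range[2])
      frac <- stats::runif(1, 0.1, 0.2)
      two_cycle_eff <- (2000 / f) * (1 + frac)
      total <- min(22, two_cycle_eff + stats::runif(1, 4, 8))
      p <- crackle_params(
        onset_s = stats::runif(1, 0.5, dur - 0.5),
        oscillation_freq_hz = f,
        total_duration_ms = total,
        initial_deflection_fraction = frac,
        amplitude = stats::runif(1, 0.5, 1)
      )
      events[[length(events) + 1]] <- acoustic_event(p)
    }
  }
  if (group == "wheeze_only" ||
      (group == "crackles_pm_wheeze" && wheezy_participant)) {
    n_wheeze <- stats::rpois(1, config$wheeze_rate)
    for (i in seq_len(n_wheeze)) {
      d_ms <- stats::runif(1, config$wheeze_duration_range_ms[1],
                           config$wheeze_duration_range_ms[2])
      p <- wheeze_params(
        onset_s = stats::runif(1, 0.5, dur - 0.5 - d_ms / 1000),
        dominant_freq_hz = stats::runif(1, config$wheeze_freq_range[1],
                                        config$wheeze_freq_range[2]),
        duration_ms = d_ms,
        amplitude = stats::runif(1, 0.3, 0.8),
        n_harmonics = sample(0:2, 1)
      )
      events[[length(events) + 1]] <- acoustic_event(p)
    }
  }
  events
}

#' Build a synthetic cohort manifest
#'
#' Lays out the full study structure as a tibble of recordings — one row per
#' participant x quadrant x device — with participant demographics, drawn
#' ground-truth events, per-site rendering seeds, and exclusion flags for the
#' configured number of aberrant recordings per device. The two device rows
#' of a site share the same events and rendering seed: one physical ground
#' truth, two observations. No audio is rendered here; see
#' [render_recording_row()] and [generate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed; the manifest is fully reproducible from
#'   `(config, seed)`.
#' @return A tibble with columns `recording_id`, `participant_id`, `group`,
#'   `quadrant`, `device`, `duration_s`, `excluded`, `exclusion_reason`,
#'   `site_seed`, `truth` (list-column of event lists), plus participant
#'   demographics `sex`, `age_years`, `weight_kg`.
#' @export
cohort_manifest <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n_part <- length(groups)
    participants <- tibble::tibble(
      participant_id = sprintf("P%02d", seq_len(n_part)),
      group = groups,
      sex = {
        s <- rep("male", n_part)
        s[sample.int(n_part, min(config$n_female, n_part))] <- "female"
        s
      },
      age_years = round(stats::rlnorm(n_part, log(6.7), 0.55), 1),
      weight_kg = round(2.4 * stats::rlnorm(n_part, log(6.7), 0.55) + 7 +
                          stats::rnorm(n_part, 0, 2), 1),
      wheezy = stats::runif(n_part) < config$wheeze_given_crackles
    )

    sites <- tidyr::expand_grid(
      participant_id = participants$participant_id,
      quadrant = config$quadrants
    )
    sites <- dplyr::left_join(sites, participants, by = "participant_id")
    sites$site_seed <- vapply(seq_len(nrow(sites)), function(i) {
      derive_seed(seed, i)
    }, numeric(1))
    sites$truth <- lapply(seq_len(nrow(sites)), function(i) {
      draw_site_events(sites$group[i], sites$wheezy[i], config)
    })

    manifest <- tidyr::expand_grid(
      site = seq_len(nrow(sites)),
      device = config$devices
    )
    manifest <- dplyr::bind_cols(
      sites[manifest$site, setdiff(names(sites), "wheezy")],
      manifest["device"]
    )
    manifest$duration_s <- config$duration_s
    manifest$recording_id <- sprintf(
      "%s_%s_%s", manifest$participant_id, manifest$quadrant, manifest$device
    )

    manifest$excluded <- FALSE
    manifest$exclusion_reason <- ""
    reasons <- c("inadequate chest wall contact", "cable connection failure")
    for (dev in config$devices) {
      rows <- which(manifest$device == dev)
      n_excl <- min(config$exclusions_per_device, length(rows))
      picked <- sample(rows, n_excl)
      manifest$excluded[picked] <- TRUE
      manifest$exclusion_reason[picked] <-
        reasons[(seq_len(n_excl) - 1) %% length(reasons) + 1]
    }

    dplyr::select(
      manifest, "recording_id", "participant_id", "group", "quadrant",
      "device", "duration_s", "excluded", "exclusion_reason", "sex",
      "age_years", "weight_kg", "site_seed", "truth"
    )
  })
}

#' Render the audio of one manifest row
#'
#' Renders the site's shared master mix at the master rate from the row's
#' `site_seed` and ground-truth events, degrades it with the row's device
#' profile, and — for rows flagged as excluded — replaces the content with an
#' aberrant signal: near-silence for "inadequate chest wall contact", hard
#' clipping at 5% of peak for "cable connection failure".
#'
#' @param row A one-row slice of a [cohort_manifest()] tibble.
#' @param config The [cohort_config()] used to build the manifest.
#' @return A [waveform()] at the device rate and depth.
#' @export
render_recording_row <- function(row, config = cohort_config()) {
  rec <- render_recording(
    row$truth[[1]],
    duration_s = row$duration_s, sample_rate_hz = config$master_rate_hz,
    snr_db = config$snr_db, cycle_period_s = config$cycle_period_s,
    seed = row$site_seed
  )
  w <- rec$waveform
  if (isTRUE(row$excluded)) {
    x <- w$samples
    if (grepl("chest wall", row$exclusion_reason)) {
      x <- x * 1e-3
    } else {
      lim <- 0.05 * max(abs(x))
      x <- pmin(pmax(x, -lim), lim)
    }
    w <- waveform(x, w$sample_rate_hz)
  }
  apply_device_profile(w, device_profile(row$device))
}

#' Generate a cohort on disk
#'
#' Builds a [cohort_manifest()], renders every recording, and writes one WAV
#' per recording (PCM16 for the low-fidelity profile, float32 for the
#' high-fidelity one), a JSON truth-annotation file per recording, and a
#' manifest CSV. Byte-identical output for identical `(config, seed)`.
#'
#' @inheritParams cohort_manifest
#' @param dir Output directory, created if needed.
#' @return The manifest tibble, invisibly, with a `path` column added.
#' @export
generate_cohort <- function(dir, config = cohort_config(), seed = 1) {
  manifest <- cohort_manifest(config, seed)
  dir.create(file.path(dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  manifest$path <- file.path(dir, "audio",
                             paste0(manifest$recording_id, ".wav"))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    w <- render_recording_row(row, config)
    write_wav(w, row$path)
    jsonlite::write_json(
      lapply(row$truth[[1]], function(ev) {
        c(list(kind = ev$kind, onset_s = ev$onset_s,
               duration_s = ev$duration_s),
          unclass(ev$params)[setdiff(names(ev$params), "onset_s")])
      }),
      file.path(dir, "truth", paste0(row$recording_id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_csv(
    dplyr::select(manifest, "recording_id", "participant_id", "group",
                  "quadrant", "device", "duration_s", "excluded",
                  "exclusion_reason"),
    file.path(dir, "manifest.csv")
  )
  invisible(manifest)
}
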