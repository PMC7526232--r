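test_that("crackle model: two-cycle duration and damping envelope", {
  # two-cycle duration is fixed by the oscillation frequency
  expect_equal(crackle_params(oscillation_freq_hz = 200)$two_cycle_duration_ms, 10)
  expect_error(crackle_params(amplitude = 0), "amplitude")
  expect_error(crackle_params(oscillation_freq_hz = -5), "must be > 0")
  expect_error(
    crackle_params(oscillation_freq_hz = 100, total_duration_ms = 15),
    "two-cycle"
  )

  # the envelope reaches 10% of peak at the nominal total duration: with
  # tau = (total - deflection) / ln 10 the closed form gives exactly
  # amplitude / 10 at t = total, so no later sample may exceed it
  p <- crackle_params(oscillation_freq_hz = 400, total_duration_ms = 20,
                      amplitude = 1)
  w <- synth_crackle(p, 44100)
  t <- wave_times(w)
  expect_lte(max(abs(w$samples[t >= 0.020])), 0.1 + 1e-9)
  expect_gt(max(abs(w$samples)), 0.9) # peak near the nominal amplitude
  expect_gte(duration_s(w), 0.020)

  expect_error(synth_crackle(p, 1000), "at least 4x")
})

test_that("wheeze model: dominant frequency, RMS and Nyquist guard", {
  p <- wheeze_params(dominant_freq_hz = 400, duration_ms = 200)
  w <- synth_wheeze(p, 4000)
  expect_equal(length(w$samples), 800)
  # periodogram peak within one bin (5 Hz here) of the dominant frequency
  expect_lte(abs(periodogram_peak_hz(w$samples, 4000) - 400), 4000 / 800)

  # pure tone RMS ~ amplitude / sqrt(2) for long segments
  long <- synth_wheeze(
    wheeze_params(dominant_freq_hz = 300, duration_ms = 2000, amplitude = 0.5,
                  n_harmonics = 0),
    8000
  )
  expect_lt(abs(sqrt(mean(long$samples^2)) - 0.5 / sqrt(2)) / (0.5 / sqrt(2)),
            0.05)

  expect_error(
    synth_wheeze(wheeze_params(dominant_freq_hz = 2500), 4000),
    "Nyquist"
  )
  # harmonics are weaker than the fundamental, so the peak stays put
  h <- synth_wheeze(
    wheeze_params(dominant_freq_hz = 250, duration_ms = 1000, n_harmonics = 2),
    8000
  )
  expect_lte(abs(periodogram_peak_hz(h$samples, 8000) - 250), 8000 / 8000)
})

test_that("breath noise is reproducible, band-limited and cycle-modulated", {
  a <- synth_breath_noise(2, cycle_period_s = 0.5, sample_rate_hz = 8000,
                          seed = 5)
  b <- synth_breath_noise(2, cycle_period_s = 0.5, sample_rate_hz = 8000,
                          seed = 5)
  expect_identical(a$samples, b$samples)
  c <- synth_breath_noise(2, cycle_period_s = 0.5, sample_rate_hz = 8000,
                          seed = 6)
  expect_false(identical(a$samples, c$samples))

  # energy below 50 Hz is a negligible fraction of the total
  mag2 <- Mod(stats::fft(a$samples))[seq_len(8000)]^2
  freq <- (seq_len(8000) - 1) * 8000 / 16000
  expect_lt(sum(mag2[freq < 50]) / sum(mag2), 0.05)

  # breath-cycle envelope: energy rises and falls with the configured period
  env <- vapply(split(a$samples^2, rep(1:20, each = 800)), mean, numeric(1))
  expect_gt(max(env) / min(env), 3)
})

test_that("render_recording mixes events at the requested SNR", {
  noise_only <- render_recording(list(), duration_s = 4, seed = 21)
  expect_identical(
    noise_only$waveform$samples,
    synth_breath_noise(4, 3, 44100, seed = 21, rms = 0.1)$samples
  )

  ev <- acoustic_event(crackle_params(onset_s = 2, oscillation_freq_hz = 300,
                                      total_duration_ms = 18))
  rec <- render_recording(list(ev), duration_s = 4, snr_db = 20, seed = 21)
  expect_length(rec$events, 1)
  expect_equal(rec$events[[1]]$onset_s, 2)

  # recover the event by subtracting the identically-seeded noise and check
  # the power ratio over the event support; the mix may have been rescaled
  # globally to stay inside full scale, so the scale factor is estimated
  # from an event-free stretch first (ratios are preserved by rescaling)
  far <- 1:4000
  a <- stats::median(rec$waveform$samples[far] /
                       noise_only$waveform$samples[far])
  event_sig <- rec$waveform$samples / a - noise_only$waveform$samples
  idx <- which(abs(event_sig) > 1e-9)
  snr_meas <- 10 * log10(
    mean(event_sig[idx]^2) / mean(noise_only$waveform$samples[idx]^2)
  )
  expect_lt(abs(snr_meas - 20), 1)

  late <- acoustic_event(wheeze_params(onset_s = 3.9, duration_ms = 300))
  expect_error(render_recording(list(late), duration_s = 4), "exceeds")
})

test_that("device profiles resample, quantize and refuse upsampling", {
  profiles <- device_profiles()
  expect_setequal(profiles$name, c("hifi", "lofi"))
  expect_equal(device_profile("lofi")$sample_rate_hz, 4000)
  expect_equal(device_profile("lofi")$bit_depth, 16L)
  expect_equal(device_profile("hifi")$sample_rate_hz, 44100)
  expect_equal(device_profile("hifi")$bit_depth, 32L)
  expect_error(device_profile("ultra"), "unknown")

  w <- test_tone(300, 8000, dur_s = 1)
  ident <- apply_device_profile(
    w, list(sample_rate_hz = 8000, bit_depth = "continuous")
  )
  expect_equal(ident$samples, w$samples)

  q <- apply_device_profile(w, list(sample_rate_hz = 8000, bit_depth = 16))
  expect_lte(max(abs(q$samples - w$samples)), 2^-15)

  # content above the target Nyquist is suppressed by the anti-alias filter
  hi_tone <- test_tone(2500, 44100, dur_s = 1)
  down <- apply_device_profile(hi_tone, device_profile("lofi"))
  expect_equal(down$sample_rate_hz, 4000)
  expect_lt(rms_mid(down$samples) / rms_mid(hi_tone$samples), 0.01)
  # and in-band content passes nearly untouched
  lo_tone <- test_tone(400, 44100, dur_s = 1)
  down2 <- apply_device_profile(lo_tone, device_profile("lofi"))
  expect_lt(abs(rms_mid(down2$samples) / rms_mid(lo_tone$samples) - 1), 0.05)

  expect_error(
    apply_device_profile(test_tone(100, 4000), device_profile("hifi")),
    "upsampling"
  )
})

test_that("cohort manifest has the study shape and obeys group rules", {
  m <- cohort_manifest(seed = 1)
  expect_equal(nrow(m), 25 * 4 * 2)
  expect_equal(sum(!m$excluded), 192)
  expect_equal(length(unique(m$participant_id)), 25)
  expect_equal(sum(m$excluded & m$device == "hifi"), 4)
  expect_equal(sum(m$excluded & m$device == "lofi"), 4)
  expect_true(all(m$exclusion_reason[m$excluded] != ""))
  expect_equal(
    sum(dplyr::distinct(m, participant_id, group)$group == "cf_clear"), 6
  )

  # group/event consistency and morphology bounds on every drawn event
  for (i in seq_len(nrow(m))) {
    evs <- m$truth[[i]]
    kinds <- vapply(evs, `[[`, character(1), "kind")
    if (m$group[i] %in% c("normal", "cf_clear")) {
      expect_length(evs, 0)
    }
    if (m$group[i] == "wheeze_only") {
      expect_false(any(kinds == "crackle"))
    }
    for (ev in evs) {
      if (ev$kind == "crackle") {
        expect_lt(ev$params$two_cycle_duration_ms, 20)
        expect_lt(ev$params$total_duration_ms, 25)
        expect_lt(ev$params$two_cycle_duration_ms, ev$params$total_duration_ms)
      } else {
        expect_gt(ev$params$duration_ms, 25)
        expect_gt(ev$params$dominant_freq_hz, 100)
      }
      expect_lte(ev$onset_s + ev$duration_s, m$duration_s[i])
    }
  }

  # both device rows of a site share ground truth and rendering seed
  one_site <- dplyr::filter(m, m$participant_id == "P10",
                            m$quadrant == "left_upper")
  expect_equal(nrow(one_site), 2)
  expect_identical(one_site$truth[[1]], one_site$truth[[2]])
  expect_identical(one_site$site_seed[1], one_site$site_seed[2])

  # manifest accounting for a non-default shape
  cfg <- cohort_config(group_sizes = c(normal = 1, wheeze_only = 0,
                                       crackles_pm_wheeze = 0, cf_clear = 0))
  m1 <- cohort_manifest(cfg, seed = 3)
  expect_equal(nrow(m1), 1 * 4 * 2)
  expect_true(all(lengths(m1$truth) == 0))

  expect_error(
    cohort_config(group_sizes = c(normal = 0, wheeze_only = 0,
                                  crackles_pm_wheeze = 0, cf_clear = 0)),
    "sum"
  )

  expect_identical(cohort_manifest(seed = 7), cohort_manifest(seed = 7))
})

test_that("generate_cohort writes a reproducible WAV/JSON/CSV bundle", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(d1, cfg, seed = 4)
  m2 <- generate_cohort(d2, cfg, seed = 4)
  expect_equal(nrow(m1), 3 * 1 * 2)
  expect_true(all(file.exists(m1$path)))
  expect_true(file.exists(file.path(d1, "manifest.csv")))

  # byte-identical audio for identical (config, seed)
  for (i in seq_len(nrow(m1))) {
    expect_identical(
      unname(tools::md5sum(m1$path[i])), unname(tools::md5sum(m2$path[i]))
    )
  }

  # device encodings round-trip with the right metadata
  hifi_path <- m1$path[m1$device == "hifi"][1]
  lofi_path <- m1$path[m1$device == "lofi"][1]
  expect_equal(read_wav(hifi_path)$sample_rate_hz, 44100)
  expect_equal(read_wav(hifi_path)$bit_depth, 32L)
  expect_equal(read_wav(lofi_path)$sample_rate_hz, 4000)
  expect_equal(read_wav(lofi_path)$bit_depth, 16L)

  # truth annotations mirror the manifest events
  wz <- m1[m1$group == "wheeze_only" & m1$device == "hifi", ]
  ann <- jsonlite::read_json(
    file.path(d1, "truth", paste0(wz$recording_id[1], ".json"))
  )
  expect_length(ann, length(wz$truth[[1]]))
  if (length(ann)) {
    expect_equal(ann[[1]]$kind, wz$truth[[1]][[1]]$kind)
    expect_equal(ann[[1]]$onset_s, wz$truth[[1]][[1]]$onset_s)
  }
})
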