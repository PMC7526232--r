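# Deterministic test signals.

test_tone <- function(freq_hz, fs, dur_s = 2, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq_hz * (0:(round(dur_s * fs) - 1)) / fs), fs)
}

# RMS over the central half of a vector, avoiding filter edge transients.
rms_mid <- function(x) {
  n <- length(x)
  sqrt(mean(x[round(n * 0.25):round(n * 0.75)]^2))
}

# Frequency of the periodogram peak of a signal.
periodogram_peak_hz <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  freq[which.max(mag)]
}

# A crackle embedded in breath noise, returning the waveform and the truth.
crackle_in_noise <- function(onset_s = 2, freq_hz = 300, total_ms = 18,
                             snr_db = 20, dur_s = 4, fs = 44100, seed = 11) {
  ev <- acoustic_event(crackle_params(
    onset_s = onset_s, oscillation_freq_hz = freq_hz,
    total_duration_ms = total_ms
  ))
  render_recording(list(ev), duration_s = dur_s, sample_rate_hz = fs,
                   snr_db = snr_db, seed = seed)
}
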