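# Deterministic synthetic test signals (built in code, no fixtures on disk).

fs_test <- 22050

# sinusoidally AM-modulated carrier, unit depth by default
am_tone <- function(rate, carrier = 1000, dur = 3, depth = 1, fs = fs_test) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  (1 + depth * sin(2 * pi * rate * t)) / 2 * sin(2 * pi * carrier * t)
}

am_noise <- function(rate, dur = 3, depth = 1, fs = fs_test, seed = 1) {
  set.seed(seed)
  t <- (seq_len(round(dur * fs)) - 1) / fs
  (1 + depth * sin(2 * pi * rate * t)) / 2 * rnorm(length(t))
}

as_clip <- function(x, id = "test") {
  x <- x / max(abs(x))
  clip <- audio_clip(id, x * (0.1 / sqrt(mean((x * 0.1 / sqrt(mean(x^2)))^2 / 1))),
                     fs_test)
  # normalize RMS to 0.1 exactly, matching preprocess_clip's contract
  clip$waveform <- clip$waveform * (0.1 / sqrt(mean(clip$waveform^2)))
  clip
}

sawtooth <- function(f0, dur = 2, fs = fs_test) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  2 * ((t * f0) %% 1) - 1
}

# envelope-spectrum frequency axis (Hz) for the default parameters
env_freqs <- function(p = feature_params()) {
  (seq_len(p$env_nfft) - 1) * (fs_test / p$env_decim) / p$env_nfft
}
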