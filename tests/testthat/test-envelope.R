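p_def <- feature_params()

test_that("the envelope of a 5 Hz AM tone oscillates at 5 Hz", {
  clip <- as_clip(am_tone(5, dur = 3))
  ch <- chunk_signal(clip)
  env <- vocalic_envelope(ch$chunks[, 1], p_def)
  expect_false(env$degenerate)
  expect_equal(length(env$values), 221)
  expect_equal(env$rate, 220.5)
  expect_equal(min(env$values), -1)
  expect_equal(max(env$values), 1)
  # independent periodogram oracle on the envelope itself
  sp <- Mod(fft(env$values * tukey_window(221, 0.1)))[1:110]
  f_peak <- (which.max(sp[-1])) * 220.5 / 221
  expect_lt(abs(f_peak - 5), 1.1)
})

test_that("an unmodulated tone gives a degenerate (flagged, all-zero) envelope", {
  clip <- as_clip(am_tone(5, depth = 0, dur = 1))
  env <- vocalic_envelope(clip$waveform[1:22050], p_def)
  expect_true(env$degenerate)
  expect_equal(env$values, rep(0, 221))
})

test_that("carriers below the vocalic band are rejected by the band-pass", {
  in_band <- as_clip(am_tone(5, carrier = 1000, dur = 1))
  below <- as_clip(am_tone(5, carrier = 100, dur = 1))
  # compare pre-normalization envelope power via the analytic band signal
  pow_of <- function(clip) {
    X <- mvfft(matrix(clip$waveform[1:22050], ncol = 1))
    ec <- vocrhythm:::envelope_core(matrix(clip$waveform[1:22050], ncol = 1), p_def, X)
    ec$degenerate[1]
  }
  expect_false(pow_of(in_band))  # modulation survives
  expect_true(pow_of(below))     # carrier rejected: envelope flat -> degenerate
})

test_that("the envelope spectrum recovers the AM rate within one bin", {
  clip <- as_clip(am_tone(5, dur = 3))
  feats <- envelope_spectrum(chunk_signal(clip), p_def)
  expect_length(feats, 93)
  df <- 220.5 / 2048
  f_hat <- (which.max(feats[-1])) * df
  expect_lt(abs(f_hat - 5), 0.15)
})

test_that("pulsed noise has more 4 Hz envelope energy than unpulsed noise", {
  pulsed <- as_clip(am_noise(4, dur = 3, seed = 11))
  flat <- as_clip(am_noise(4, depth = 0, dur = 3, seed = 12))
  df <- 220.5 / 2048
  bin4 <- round(4 / df) + 1
  e_pulsed <- envelope_spectrum(chunk_signal(pulsed), p_def)[bin4]
  e_flat <- envelope_spectrum(chunk_signal(flat), p_def)[bin4]
  expect_gt(e_pulsed, e_flat)
})

test_that("envelope features are invariant to input gain after preprocessing", {
  set.seed(21)
  x <- am_noise(6, dur = 2, seed = 21)
  a <- preprocess_clip(audio_clip("a", x, 22050), 3)
  b <- preprocess_clip(audio_clip("b", 3.7 * x, 22050), 3)
  expect_equal(envelope_spectrum(chunk_signal(a), p_def),
               envelope_spectrum(chunk_signal(b), p_def), tolerance = 1e-9)
})
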