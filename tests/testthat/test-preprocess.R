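make_manifest_csv <- function(rows, check_files = FALSE) {
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  load_manifest(f, check_files = check_files)
}

test_that("manifest validation enforces unique ids and type-class consistency", {
  ok <- data.frame(id = paste0("c", 1:5), path = paste0("c", 1:5, ".wav"),
                   voc_type = c("a", "a", "b", "b", "b"),
                   class_label = c("+cognition", "+cognition", rep("-cognition", 3)))
  m <- make_manifest_csv(ok)
  expect_s3_class(m, "voc_manifest")
  expect_equal(nrow(m), 5)

  dup <- ok; dup$id[2] <- "c1"
  expect_error(make_manifest_csv(dup), "duplicate")

  both <- ok; both$class_label[2] <- "-cognition"
  expect_error(make_manifest_csv(both), "both classes")

  badlab <- ok; badlab$class_label[1] <- "positive"
  expect_error(make_manifest_csv(badlab), "class_label")
})

test_that("a 5-type manifest mirroring the study structure loads with class sizes 3 and 2", {
  rows <- data.frame(
    id = paste0("v", 1:5), path = paste0("v", 1:5, ".wav"),
    voc_type = c("english", "german", "lemur", "cantonese", "finch"),
    class_label = c(rep("+cognition", 3), rep("-cognition", 2)))
  m <- make_manifest_csv(rows)
  cls <- tapply(m$class_label, m$voc_type, `[`, 1)
  expect_equal(sum(cls == "+cognition"), 3)
  expect_equal(sum(cls == "-cognition"), 2)
})

test_that("preprocessing tiles to the target duration at the target RMS", {
  set.seed(1)
  clip <- audio_clip("a", rnorm(2 * 22050), 22050)
  out <- preprocess_clip(clip, 9.54)
  expect_equal(length(out$waveform), 210357)  # round(9.54 * 22050)
  expect_equal(sqrt(mean(out$waveform^2)), 0.1, tolerance = 1e-6)
  # tiling periodicity: out[k] == out[k + L] for the first tiles
  L <- 2 * 22050
  expect_equal(out$waveform[1:L], out$waveform[(L + 1):(2 * L)])
})

test_that("preprocessing is an identity on already-conforming clips", {
  set.seed(2)
  x <- rnorm(210357); x <- x * (0.1 / sqrt(mean(x^2)))
  clip <- audio_clip("b", x, 22050)
  out <- preprocess_clip(clip, 9.54)
  expect_equal(out$waveform, x, tolerance = 1e-12)
})

test_that("preprocessing removes input gain exactly", {
  set.seed(3)
  x <- rnorm(22050)
  a <- preprocess_clip(audio_clip("g1", x, 22050), 2)
  b <- preprocess_clip(audio_clip("g2", 2 * x, 22050), 2)
  expect_equal(a$waveform, b$waveform, tolerance = 1e-9)
})

test_that("silent clips are rejected", {
  expect_error(preprocess_clip(audio_clip("s", rep(0, 100), 22050), 1), "silent")
})

test_that("resampling keeps a tone at its frequency", {
  fs_in <- 44100
  t <- (0:(2 * fs_in - 1)) / fs_in
  clip <- audio_clip("r", sin(2 * pi * 1000 * t), fs_in)
  out <- preprocess_clip(clip, 2)
  expect_equal(out$sample_rate, 22050)
  sp <- Mod(fft(out$waveform[1:22050]))[1:11025]
  expect_equal(which.max(sp) - 1, 1000, tolerance = 1)
})

test_that("chunking yields floor(L/22050) one-second bins that conserve the signal", {
  set.seed(4)
  clip <- preprocess_clip(audio_clip("c", rnorm(3 * 22050), 22050), 9.54)
  ch <- chunk_signal(clip)
  expect_equal(ncol(ch$chunks), 9)          # floor(210357 / 22050)
  expect_equal(nrow(ch$chunks), 22050)
  expect_equal(as.vector(ch$chunks), clip$waveform[1:(9 * 22050)])

  exact <- preprocess_clip(audio_clip("e", rnorm(3 * 22050), 22050), 3)
  che <- chunk_signal(exact)
  expect_equal(ncol(che$chunks), 3)
  expect_equal(as.vector(che$chunks), exact$waveform)

  short <- audio_clip("s", rnorm(11025) + 1, 22050)
  expect_error(chunk_signal(short), "shorter than one")
})
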