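test_that("identical spec and seed give identical clips; datasets are byte-reproducible", {
  sp <- synth_spec("t", "+cognition", syllable_rate = 4)
  a <- generate_clip(sp, seed = 5)
  b <- generate_clip(sp, seed = 5)
  expect_identical(a$waveform, b$waveform)
  expect_false(identical(a$waveform, generate_clip(sp, seed = 6)$waveform))

  d1 <- file.path(tempdir(), "synrep1"); d2 <- file.path(tempdir(), "synrep2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(dataset_preset("null", n_per_type = 2, seed = 44), d1)
  generate_dataset(dataset_preset("null", n_per_type = 2, seed = 44), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("datasets have the documented bookkeeping structure", {
  man <- cached_dataset("null", 2, 900)
  expect_equal(nrow(man), 10)
  cls <- table(man$class_label)
  expect_equal(unname(cls[["+cognition"]]), 6)
  expect_equal(unname(cls[["-cognition"]]), 4)
  expect_equal(length(unique(man$voc_type)), 5)
  expect_true(all(file.exists(man$path)))
})

test_that("spec validation rejects out-of-band parameters", {
  expect_error(synth_spec("t", "+cognition", syllable_rate = 12), "1-10")
  expect_error(synth_spec("t", "+cognition", syllable_shape = 1.2), "\\(0, 1\\)")
  expect_error(synth_spec("t", "+cognition", f0_base = 2000), "50-1000")
  expect_error(synth_spec("t", "+cognition",
                          resonances = list(c(12000, 100, 5))), "Nyquist")
})

test_that("single-axis presets differ across classes only along their axis", {
  for (nm in c("rhythm_only", "spectral_only", "pitch_only", "null")) {
    pr <- dataset_preset(nm, n_per_type = 1, seed = 1)
    flat <- lapply(pr$specs, function(s) s[setdiff(names(s), c("type_name", "class_label"))])
    varying <- names(flat[[1]])[vapply(names(flat[[1]]), function(f)
      length(unique(lapply(flat, `[[`, f))) > 1, TRUE)]
    expected <- switch(nm, rhythm_only = "syllable_rate",
                       spectral_only = "resonances",
                       pitch_only = "f0_base", null = character(0))
    expect_equal(varying, expected, label = nm)
  }
})

test_that("empirical durations track the specified lognormal means", {
  sp <- synth_spec("t", "+cognition", duration_mean = 2, duration_sigma = 0.5)
  durs <- vapply(1:100, function(s) clip_duration(generate_clip(sp, seed = s)),
                 numeric(1))
  expect_lt(abs(mean(durs) - 2) / 2, 0.1)
  expect_true(all(durs >= 0.5 & durs <= 9.54))
})

test_that("the generated clip's syllable rate and f0 are recoverable end to end", {
  p <- feature_params()
  sp <- synth_spec("t", "+cognition", syllable_rate = 4, f0_base = 220,
                   f0_excursion = 0, harmonic_count = 40, am_floor = 0.25)
  clip <- preprocess_clip(generate_clip(sp, seed = 8), 9.54)
  env <- envelope_spectrum(chunk_signal(clip), p)
  f_hat <- (which.max(env[-1])) * (220.5 / 2048)
  expect_lt(abs(f_hat - 4), 0.2)
  expect_lt(abs(median(f0_contour(clip, p)) - 220), 2)
})

test_that("in rhythm_only the per-class f0 distributions are indistinguishable", {
  man <- rhythm_manifest()
  blk <- cached_features("rhythm_only", 60, 102, "pitch")
  med <- apply(blk$matrix, 1, median)
  y <- man$class_label[match(blk$sample_ids, man$id)] == "+cognition"
  expect_gt(wilcox.test(med[y], med[!y])$p.value, 0.01)
})
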