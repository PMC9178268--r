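# Feature assembly and the feature-level dissociation properties.

tiny_manifest <- function() cached_dataset("null", 2, 900)

test_that("full blocks concatenate the three family blocks, aligned to the manifest", {
  man <- tiny_manifest()
  cache <- file.path(test_cache_dir(), "tiny_features")
  full <- assemble_features(man, "full", target_duration = 9.54, cache_dir = cache)
  rhythmic <- assemble_features(man, "rhythmic", target_duration = 9.54, cache_dir = cache)
  spectral <- assemble_features(man, "spectral", target_duration = 9.54, cache_dir = cache)
  pitch <- assemble_features(man, "pitch", target_duration = 9.54, cache_dir = cache)
  expect_equal(ncol(full$matrix),
               ncol(rhythmic$matrix) + ncol(spectral$matrix) + ncol(pitch$matrix))
  expect_equal(full$sample_ids, man$id)
  expect_false(anyDuplicated(full$dim_names) > 0)
  # slicing the full block reproduces each family block exactly
  expect_equal(subset_features(full, "rhythmic")$matrix, rhythmic$matrix)
  expect_equal(subset_features(full, "spectral")$matrix, spectral$matrix)
  expect_equal(subset_features(full, "pitch")$matrix, pitch$matrix)
})

test_that("row order follows the manifest and caching is bit-exact", {
  man <- tiny_manifest()
  cache <- file.path(test_cache_dir(), "tiny_features")
  pitch <- assemble_features(man, "pitch", target_duration = 9.54, cache_dir = cache)
  perm <- man[rev(seq_len(nrow(man))), ]
  class(perm) <- class(man)
  pitch_rev <- assemble_features(perm, "pitch", target_duration = 9.54)
  expect_equal(pitch_rev$matrix, pitch$matrix[rev(seq_len(nrow(man))), ])
  cached <- assemble_features(man, "pitch", target_duration = 9.54, cache_dir = cache)
  expect_identical(cached$matrix, pitch$matrix)
})

test_that("AM rate moves rhythmic features but barely moves the f0 contour", {
  mk <- function(rate) {
    src <- sawtooth(220, dur = 3)
    t <- (seq_along(src) - 1) / fs_test
    env <- 0.3 + 0.7 * (1 + sin(2 * pi * rate * t)) / 2
    preprocess_clip(audio_clip(paste0("r", rate), src * env, fs_test), 3)
  }
  a <- mk(4); b <- mk(6.5)
  rel <- function(u, v) sqrt(sum((u - v)^2)) / sqrt(sum(u^2))
  p <- feature_params()
  rhythm_a <- c(envelope_spectrum(chunk_signal(a), p),
                temporal_modulation_spectrum(chunk_signal(a), p))
  rhythm_b <- c(envelope_spectrum(chunk_signal(b), p),
                temporal_modulation_spectrum(chunk_signal(b), p))
  expect_gt(rel(rhythm_a, rhythm_b), 0.1)
  expect_lt(rel(f0_contour(a, p), f0_contour(b, p)), 0.05)
})

test_that("f0 moves the pitch contour but barely moves ENV and TMS", {
  mk <- function(f0) {
    src <- sawtooth(f0, dur = 3)
    t <- (seq_along(src) - 1) / fs_test
    env <- 0.3 + 0.7 * (1 + sin(2 * pi * 5 * t)) / 2
    preprocess_clip(audio_clip(paste0("f", f0), src * env, fs_test), 3)
  }
  a <- mk(220); b <- mk(260)
  rel <- function(u, v) sqrt(sum((u - v)^2)) / sqrt(sum(u^2))
  p <- feature_params()
  expect_gt(rel(f0_contour(a, p), f0_contour(b, p)), 0.1)
  expect_lt(rel(envelope_spectrum(chunk_signal(a), p),
                envelope_spectrum(chunk_signal(b), p)), 0.05)
  expect_lt(rel(temporal_modulation_spectrum(chunk_signal(a), p),
                temporal_modulation_spectrum(chunk_signal(b), p)), 0.05)
})
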