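# Shared synthetic datasets and feature blocks, generated once per test
# session and cached on disk under tempdir() so every test file can reuse
# them without re-extraction.

test_cache_dir <- function() {
  d <- file.path(tempdir(), "vocrhythm-test-cache")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# manifest for a generated preset dataset (cached)
cached_dataset <- function(preset, n_per_type, seed) {
  dir <- file.path(test_cache_dir(), sprintf("%s_n%d_s%d", preset, n_per_type, seed))
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    generate_dataset(dataset_preset(preset, n_per_type = n_per_type, seed = seed), dir)
  load_manifest(mf)
}

# feature block for a cached dataset (cached; duration pinned to 9.54 s)
cached_features <- function(preset, n_per_type, seed, feature_class) {
  dir <- file.path(test_cache_dir(), sprintf("%s_n%d_s%d", preset, n_per_type, seed))
  man <- cached_dataset(preset, n_per_type, seed)
  assemble_features(man, feature_class, target_duration = 9.54,
                    cache_dir = file.path(dir, "features"))
}

# the acceptance-scale datasets, shared across test files
full_manifest <- function() cached_dataset("full", 100, 101)
rhythm_manifest <- function() cached_dataset("rhythm_only", 60, 102)
null_manifest <- function() cached_dataset("null", 60, 103)
pitchonly_manifest <- function() cached_dataset("pitch_only", 30, 104)

# small quota for reduced-scale property checks (class totals 60/60)
small_quota <- function(manifest) default_quota(manifest, per_plus = 20, per_minus = 30)
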