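#!/usr/bin/env Rscript
# Step 2: extract acoustic features.
#
# Every clip is intensity-normalized, resampled to 22,050 Hz, tiled to the
# common 9.54-s duration, and passed through the three feature families:
# rhythmic (envelope spectrum, envelope-IMF spectra, temporal modulation
# spectrum, second-order scattering), spectral envelope (MFCC, first-order
# scattering), and pitch (NCF f0 contour). Full blocks are cached under
# results/features/<preset>/ and sliced per class downstream.

suppressPackageStartupMessages(library(vocrhythm))
suppressPackageStartupMessages(library(optparse))

opt <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character", default = "data"),
  make_option("--out", type = "character", default = "results/features"),
  make_option("--target_duration", type = "double", default = 9.54,
              help = "duration-normalization target in seconds [default %default]")
)))

for (preset in c("full", "rhythm_only", "pitch_only", "null")) {
  mf <- file.path(opt$data, preset, "manifest.csv")
  if (!file.exists(mf)) { cat("skipping", preset, "(no manifest)\n"); next }
  man <- load_manifest(mf)
  blk <- assemble_features(man, "full", target_duration = opt$target_duration,
                           cache_dir = file.path(opt$out, preset), progress = TRUE)
  cat(sprintf("%-12s %4d clips x %5d feature dims\n",
              preset, nrow(blk$matrix), ncol(blk$matrix)))
}
cat("done: feature blocks cached under", opt$out, "\n")
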