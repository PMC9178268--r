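# vocrhythm

Which surface acoustics separate vocalizations that support infant
cognition from those that do not? Behavioral work shows that some signals
(e.g., infant-directed English or German, lemur calls) facilitate object
categorization in young infants while others (e.g., Cantonese ID speech,
zebra finch song — from the vantage point of English-learning infants) do
not. If that functional contrast has an acoustic signature, a classifier
restricted to a single family of acoustic features can reveal *which*
acoustics carry it. `vocrhythm` implements the full analysis as an R
package plus a scripted workflow:

* **Feature families** — *rhythmic*: amplitude-envelope spectrum (ENV),
  empirical-mode-decomposition spectra of the envelope (IMF1 ≈ syllabic,
  IMF2 ≈ supra-syllabic), temporal modulation spectrum (TMS), second-order
  wavelet scattering (WTS2); *spectral envelope*: MFCC and first-order
  scattering (WTS1); *pitch*: frame-wise normalized-correlation f0.
* **Classification** — Monte Carlo cross-validation: per-type undersampling
  to balanced classes (60/60/40/40/40 → 240 samples), stratified 75:25
  split, train-only PCA keeping components that explain 95% of variance,
  and nested 4-fold selection over lasso, decision tree, SVM, ridge, and
  naive Bayes with fixed hyperparameter grids. Metrics: AUC (the
  probability that a random positive outscores a random negative), ACC,
  sensitivity, specificity, and per-type confusion percentages.
* **Significance** — label-permutation testing: the p-value is the fraction
  of permuted-label AUCs at or above the observed mean AUC.
* **Synthetic vocalizations** — a generator with independently switchable
  class separations in syllable rate, spectral resonances, and f0, so the
  whole pipeline is testable as parameter recovery without any private
  corpora.

## Worked example

Generate a small dataset in which only the syllable rate separates the
classes, then compare a rhythm-based and a pitch-based classifier:

```r
library(vocrhythm)

dir <- file.path(tempdir(), "demo")
man <- generate_dataset(dataset_preset("rhythm_only", n_per_type = 60, seed = 31), dir)

blk <- assemble_features(man, "full", target_duration = 9.54,
                         cache_dir = file.path(dir, "features"))

run_mccv(subset_features(blk, "rhythmic"), man, n_iter = 10, seed = 5)
#> <mccv_result 'rhythmic'> 10 iterations
#>   mean   AUC 0.9999  ACC 0.9917  sens 0.9867  spec 0.9967
#>   median AUC 1.0000  ACC 0.9917  sens 1.0000  spec 1.0000

run_mccv(subset_features(blk, "pitch"), man, n_iter = 10, seed = 5)
#> <mccv_result 'pitch'> 10 iterations
#>   mean   AUC 0.5342  ACC 0.5333  sens 0.4767  spec 0.5900
#>   median AUC 0.5378  ACC 0.5333  sens 0.5167  spec 0.5833
```

The rhythmic model recovers the planted rate separation essentially
perfectly, while the pitch model sits at chance — the classes genuinely do
not differ in f0. On the `full` preset (all three axes separated) every
feature-class model classifies nearly perfectly, and on the `null` preset
(identical classes) all models drop to chance with non-significant
permutation p-values.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` → `04_permutation.R`), each writing its tables under
`results/`.

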