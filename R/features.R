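# The three acoustic feature families:
#   rhythmic  = amplitude-envelope spectrum (ENV), envelope IMF spectra (EMD),
#               temporal modulation spectrum (TMS), 2nd-order scattering (WTS2)
#   spectral  = MFCC + 1st-order scattering (WTS1)
#   pitch     = frame-wise normalized-correlation f0 contour
# All extractors are deterministic and operate on preprocessed clips
# (22,050 Hz, common RMS, duration-normalized), so each family returns a
# fixed-length vector per clip.

#' Feature extraction parameters
#'
#' Collects every tunable of the feature extractors with its default.
#' Frequencies in Hz, windows in samples at 22,050 Hz.
#'
#' @param env_band Vocalic band-pass edges for the amplitude envelope
#'   (default 400--4000 Hz; de-emphasizes glottal energy and obstruent noise).
#' @param butter_order Butterworth prototype order for envelope filters.
#' @param env_lowpass Envelope low-pass cutoff (default 10 Hz).
#' @param env_decim Envelope decimation factor (default 100, giving 220.5 Hz).
#' @param env_nfft Zero-padded FFT length for envelope/IMF spectra.
#' @param tukey_r Tukey window taper for the envelope spectrum.
#' @param env_fmax Upper edge of the retained envelope-spectrum band (Hz).
#' @param imf_band Retained band of the IMF power spectra (Hz).
#' @param emd_max_imf,emd_sift_max,emd_sd_thresh EMD controls, see [emd()].
#' @param tms_n_bands,tms_range Cochlear (gammatone) bank size and span.
#' @param tms_mod_max Highest retained modulation frequency (Hz).
#' @param scat_q1,scat_q2 Quality factors of the two scattering filter banks.
#' @param scat_fmin,scat_fmax First-order scattering bank span (Hz).
#' @param scat_lambda2 Second-order (modulation) centre frequencies (Hz).
#' @param scat_normalize Divide each second-order coefficient by its parent
#'   first-order coefficient (normalized scattering), so WTS2 carries
#'   modulation structure rather than spectral energy.
#' @param stft_win,stft_hop Analysis window and hop for MFCC / f0
#'   (default 1102 / 551 samples = 50 / 25 ms).
#' @param mfcc_nfft,mfcc_n_filt,mfcc_n_coef MFCC FFT length, mel filter count,
#'   and number of retained cepstral coefficients (DC excluded).
#' @param mfcc_abs Take the amplitude (absolute value) of the DCT coefficients.
#' @param f0_range f0 search range in Hz (default 50--1000, covering
#'   infant-directed speech through high primate calls).
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(env_band = c(400, 4000), butter_order = 4,
                           env_lowpass = 10, env_decim = 100,
                           env_nfft = 2048, tukey_r = 0.1, env_fmax = 10,
                           imf_band = c(1, 10),
                           emd_max_imf = 6, emd_sift_max = 10, emd_sd_thresh = 0.2,
                           tms_n_bands = 64, tms_range = c(80, 8820),
                           tms_mod_max = 32,
                           scat_q1 = 8, scat_q2 = 1,
                           scat_fmin = 80, scat_fmax = 9800,
                           scat_lambda2 = 2^(1:7), scat_normalize = TRUE,
                           stft_win = 1102, stft_hop = 551,
                           mfcc_nfft = 2048, mfcc_n_filt = 40, mfcc_n_coef = 13,
                           mfcc_abs = TRUE,
                           f0_range = c(50, 1000)) {
  p <- as.list(environment())
  class(p) <- "feature_params"
  p
}

env_rate <- function(p) voc_rate() / p$env_decim

# --- amplitude envelope -------------------------------------------------------

# Batched envelope of every chunk column: band-pass -> analytic magnitude ->
# low-pass -> decimate -> mean-subtract -> rescale to [-1, 1].
envelope_core <- function(chunks, p, X = NULL) {
  pl <- chunk_plan(p)
  N <- pl$N
  if (is.null(X)) X <- stats::mvfft(chunks)
  z <- stats::mvfft(X * pl$env_bp, inverse = TRUE) / N
  E <- Mod(z)
  Fe <- stats::mvfft(E) * pl$env_lp
  e <- Re(stats::mvfft(Fe, inverse = TRUE)) / N
  dec <- e[seq(1, N, by = pl$decim), , drop = FALSE]
  scale <- pmax(apply(abs(dec), 2, max), 1e-300)
  dec <- sweep(dec, 2, colMeans(dec))
  lo <- apply(dec, 2, min); hi <- apply(dec, 2, max)
  # degenerate when the envelope is flat relative to itself (constant or
  # silent input) or carries negligible energy relative to the chunk (all
  # band energy rejected by the vocalic band-pass)
  chunk_rms <- sqrt(colMeans(chunks^2))
  degenerate <- (hi - lo) / scale < 1e-6 | scale < 1e-4 * chunk_rms
  out <- matrix(0, nrow(dec), ncol(dec))
  ok <- which(!degenerate)
  if (length(ok))
    out[, ok] <- 2 * sweep(sweep(dec[, ok, drop = FALSE], 2, lo[ok]),
                           2, hi[ok] - lo[ok], "/") - 1
  list(env = out, degenerate = degenerate)
}

#' Vocalic amplitude envelope of one 1-s chunk
#'
#' Band-pass (vocalic band), analytic-signal magnitude, 10 Hz low-pass,
#' decimation by 100, mean subtraction, and min--max rescale to \[-1, 1\].
#' Degenerate chunks (constant or silent envelope) return all zeros and are
#' flagged.
#'
#' @param chunk Numeric vector of exactly 22,050 samples.
#' @param params A [feature_params()] list.
#' @return List with `values` (length 221), `rate` (220.5 Hz), `degenerate`.
#' @export
vocalic_envelope <- function(chunk, params = feature_params()) {
  stopifnot(length(chunk) == voc_rate(), all(is.finite(chunk)))
  ec <- envelope_core(matrix(chunk, ncol = 1), params)
  list(values = ec$env[, 1], rate = env_rate(params),
       degenerate = ec$degenerate[1])
}

env_spectrum_bins <- function(p) {
  n_env <- ceiling(voc_rate() / p$env_decim)
  df <- env_rate(p) / p$env_nfft
  keep <- which((seq_len(p$env_nfft) - 1) * df <= p$env_fmax)
  list(n_env = n_env, df = df, keep = keep)
}

#' Amplitude-envelope spectrum features
#'
#' Per chunk: Tukey-windowed normalized envelope, zero-padded magnitude FFT;
#' averaged across chunks; bins up to `env_fmax` retained (0.108 Hz spacing,
#' 93 dimensions at the defaults).
#'
#' @param chunks A `chunked_signal` from [chunk_signal()].
#' @param params A [feature_params()] list.
#' @return Named feature vector.
#' @export
envelope_spectrum <- function(chunks, params = feature_params()) {
  stopifnot(inherits(chunks, "chunked_signal"))
  ec <- envelope_core(chunks$chunks, params)
  env_spectrum_from_env(ec, params)
}

env_spectrum_from_env <- function(ec, p) {
  bins <- env_spectrum_bins(p)
  ok <- which(!ec$degenerate)
  if (!length(ok)) stop("no valid (non-degenerate) chunks for envelope spectrum")
  w <- tukey_window(bins$n_env, p$tukey_r)
  V <- matrix(0, p$env_nfft, length(ok))
  V[seq_len(bins$n_env), ] <- ec$env[, ok, drop = FALSE] * w
  mag <- Mod(stats::mvfft(V))[bins$keep, , drop = FALSE]
  out <- rowMeans(mag)
  names(out) <- sprintf("ENV_f%.3fHz", (bins$keep - 1) * bins$df)
  out
}

#' Envelope IMF spectrum features
#'
#' EMD is run on each chunk's normalized envelope; the averaged power spectral
#' densities of IMF1 (syllabic) and IMF2 (supra-syllabic) in the 1--10 Hz band
#' are concatenated. Chunks whose envelope is degenerate or yields fewer than
#' two modes contribute zeros.
#'
#' @inheritParams envelope_spectrum
#' @return Named feature vector (166 dimensions at the defaults).
#' @export
imf_spectra <- function(chunks, params = feature_params()) {
  stopifnot(inherits(chunks, "chunked_signal"))
  ec <- envelope_core(chunks$chunks, params)
  imf_spectra_from_env(ec, params)
}

imf_spectra_from_env <- function(ec, p) {
  bins <- env_spectrum_bins(p)
  f <- (seq_len(p$env_nfft) - 1) * bins$df
  keep <- which(f >= p$imf_band[1] & f <= p$imf_band[2])
  nb <- length(keep)
  K <- ncol(ec$env)
  acc <- numeric(2 * nb)
  fs_env <- env_rate(p)
  for (k in seq_len(K)) {
    if (ec$degenerate[k]) next
    dec <- emd(ec$env[, k], p$emd_max_imf, p$emd_sift_max, p$emd_sd_thresh)
    if (ncol(dec$imfs) < 2) next
    V <- matrix(0, p$env_nfft, 2)
    V[seq_len(bins$n_env), ] <- dec$imfs[, 1:2]
    P <- Mod(stats::mvfft(V))^2 / (bins$n_env * fs_env)
    acc <- acc + c(P[keep, 1], P[keep, 2])
  }
  out <- acc / K
  names(out) <- c(sprintf("IMF1_psd_%.3fHz", f[keep]),
                  sprintf("IMF2_psd_%.3fHz", f[keep]))
  out
}

# --- temporal modulation spectrum --------------------------------------------

#' Temporal modulation spectrum features
#'
#' Per chunk: a 64-band log-spaced gammatone-style filterbank decomposes the
#' signal; each band's analytic-signal envelope is log-compressed; the DFT
#' magnitude of each band envelope is normalized by its DC term; the TMS is
#' the RMS across bands, averaged over chunks. Modulation frequencies
#' 1..`tms_mod_max` Hz are retained (1 Hz resolution for 1-s bins).
#'
#' @inheritParams envelope_spectrum
#' @return Named feature vector (32 dimensions at the defaults).
#' @export
temporal_modulation_spectrum <- function(chunks, params = feature_params()) {
  stopifnot(inherits(chunks, "chunked_signal"))
  X <- stats::mvfft(chunks$chunks)
  tms_from_spectra(X, params)
}

tms_from_spectra <- function(X, p) {
  pl <- chunk_plan(p)
  K <- ncol(X)
  acc <- matrix(0, p$tms_mod_max + 1, K) # sum over bands of squared norm. DFT
  for (band in pl$tms_bands) {
    E <- band_envelope(X, band, pl$N)
    L <- log(E + 1e-8)
    kern <- pl$dft_kernels[[as.character(band$M)]]
    D <- sqrt((kern$re %*% L)^2 + (kern$im %*% L)^2)
    Dn <- sweep(D, 2, pmax(D[1, ], 1e-300), "/")
    acc <- acc + Dn^2
  }
  out <- rowMeans(sqrt(acc / length(pl$tms_bands)))[-1]
  names(out) <- sprintf("TMS_%dHz", seq_len(p$tms_mod_max))
  out
}

# --- wavelet scattering -------------------------------------------------------

#' Wavelet time-scattering features
#'
#' Constant-Q Gaussian wavelet scattering on consecutive 1-s chunks with a
#' 1-s invariance scale (coefficients are time-averaged within each chunk and
#' then across chunks). First-order coefficients (`wts1`) describe the
#' spectral envelope; second-order coefficients (`wts2`), taken relative to
#' their parent first-order coefficient, describe amplitude/frequency
#' modulation structure.
#'
#' @param clip A preprocessed `audio_clip`.
#' @param params A [feature_params()] list.
#' @return List with named vectors `wts1` and `wts2`.
#' @export
wavelet_scattering <- function(clip, params = feature_params()) {
  ch <- chunk_signal(clip)
  X <- stats::mvfft(ch$chunks)
  scattering_from_spectra(X, params)
}

scattering_from_spectra <- function(X, p) {
  pl <- chunk_plan(p)
  K <- ncol(X)
  n1 <- length(pl$lam1)
  S1 <- matrix(0, n1, K)                 # first-order coefficients per chunk
  S2 <- matrix(0, nrow(pl$paths), K)     # second-order, fixed path order
  path_of_band <- split(seq_len(nrow(pl$paths)), pl$paths[, 2])
  for (j1 in seq_len(n1)) {
    band <- pl$s1_bands[[j1]]
    U1 <- band_envelope(X, band, pl$N)
    S1[j1, ] <- colMeans(U1)
    rows <- path_of_band[[as.character(j1)]]
    if (is.null(rows)) next
    U1d <- if (band$M > pl$M2)
      colMeans(array(U1, c(band$M / pl$M2, pl$M2, K))) else U1
    F2 <- stats::mvfft(U1d)
    for (r in rows) {
      j2 <- pl$paths[r, 1]
      U2 <- Mod(stats::mvfft(F2 * pl$s2_H[, j2], inverse = TRUE)) / pl$M2
      S2[r, ] <- colMeans(U2)
    }
  }
  if (p$scat_normalize)
    S2 <- S2 / (S1[pl$paths[, 2], , drop = FALSE] + 1e-12)
  wts1 <- rowMeans(S1)
  wts2 <- rowMeans(S2)
  names(wts1) <- sprintf("WTS1_%.0fHz", pl$lam1)
  names(wts2) <- sprintf("WTS2_%.0fHz_m%.0fHz",
                         pl$lam1[pl$paths[, 2]], pl$lam2[pl$paths[, 1]])
  list(wts1 = wts1, wts2 = wts2)
}

# --- MFCC ---------------------------------------------------------------------

#' MFCC features
#'
#' 50-ms Hamming-windowed frames with 25-ms overlap; power spectrum; 40-filter
#' triangular mel bank; log; DCT-II keeping coefficients 1..13 (DC excluded);
#' amplitudes of the coefficients, concatenated across all frames.
#'
#' @inheritParams wavelet_scattering
#' @return Named feature vector (`n_frames * mfcc_n_coef` dimensions).
#' @export
mfcc_features <- function(clip, params = feature_params()) {
  stopifnot(inherits(clip, "audio_clip"))
  p <- params
  x <- clip$waveform
  fp <- frame_plan(length(x), p$stft_win, p$stft_hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(p$stft_win) - 1) / (p$stft_win - 1))
  key <- plan_key("melplan", p$mfcc_n_filt, p$mfcc_nfft, p$mfcc_n_coef)
  mel <- cache_get(key, function() list(
    fb = mel_filterbank(p$mfcc_n_filt, p$mfcc_nfft, voc_rate()),
    dct = dct_matrix(p$mfcc_n_coef, p$mfcc_n_filt)))
  V <- matrix(0, p$mfcc_nfft, fp$n_frames)
  V[seq_len(p$stft_win), ] <- matrix(x[fp$idx], p$stft_win) * w
  P <- Mod(stats::mvfft(V)[seq_len(p$mfcc_nfft / 2 + 1), , drop = FALSE])^2
  C <- mel$dct %*% log(mel$fb %*% P + 1e-10)
  if (p$mfcc_abs) C <- abs(C)
  out <- as.vector(C)
  names(out) <- sprintf("MFCC_w%03d_c%02d",
                        rep(seq_len(fp$n_frames), each = p$mfcc_n_coef),
                        rep(seq_len(p$mfcc_n_coef), fp$n_frames))
  out
}

# --- f0 contour ---------------------------------------------------------------

#' Frame-wise f0 contour via the normalized correlation function
#'
#' For each 50-ms frame (25-ms hop) the normalized cross-correlation over lags
#' corresponding to `f0_range` is computed; f0 is the reciprocal of the
#' best-correlated lag. No voicing decision is applied.
#'
#' @inheritParams wavelet_scattering
#' @return Named feature vector of per-frame f0 values (Hz).
#' @export
f0_contour <- function(clip, params = feature_params()) {
  stopifnot(inherits(clip, "audio_clip"))
  p <- params
  fs <- voc_rate()
  fmin <- p$f0_range[1]; fmax <- p$f0_range[2]
  if (fmin >= fmax) stop("f0 range: fmin must be < fmax")
  if (fmax > fs / 4) stop("f0 range: fmax must be at most a quarter of the sample rate")
  lag_min <- ceiling(fs / fmax); lag_max <- floor(fs / fmin)
  if (lag_max >= p$stft_win) stop("analysis window too short for fmin")
  x <- clip$waveform
  fp <- frame_plan(length(x), p$stft_win, p$stft_hop)
  Fr <- matrix(x[fp$idx], p$stft_win)
  # fixed-length correlation window W: every lag correlates the same number
  # of samples, so the normalized correlation has equal variance at all lags
  W <- p$stft_win - lag_max
  nfft <- 2048
  while (nfft < p$stft_win + 1) nfft <- nfft * 2
  V <- matrix(0, nfft, fp$n_frames)
  V[seq_len(p$stft_win), ] <- Fr
  S <- stats::mvfft(V)
  V[] <- 0
  V[seq_len(W), ] <- Fr[seq_len(W), , drop = FALSE]
  S1 <- stats::mvfft(V)
  cc <- Re(stats::mvfft(Conj(S1) * S, inverse = TRUE)) / nfft
  css <- apply(Fr^2, 2, cumsum)
  lags <- lag_min:lag_max
  E1 <- rep(css[W, ], each = length(lags))
  E2 <- css[lags + W, , drop = FALSE] - css[lags, , drop = FALSE]
  ncf <- cc[lags + 1, , drop = FALSE] / sqrt(E1 * E2 + 1e-300)
  # shortest lag that is a local maximum within 5% of the frame's peak
  # correlation: a strictly periodic frame correlates equally at every
  # multiple of its period (standard octave-bias guard)
  nl <- length(lags)
  locmax <- rbind(ncf[1, ] >= ncf[2, ],
                  ncf[2:(nl - 1), ] >= ncf[1:(nl - 2), ] &
                  ncf[2:(nl - 1), ] >= ncf[3:nl, ],
                  ncf[nl, ] >= ncf[nl - 1, ])
  peak <- ncf[cbind(max.col(t(ncf), ties.method = "first"), seq_len(ncol(ncf)))]
  cand <- locmax & ncf >= rep(0.95 * peak, each = nl)
  best <- max.col(t(cand), ties.method = "first")
  out <- fs / lags[best]
  names(out) <- sprintf("F0_w%03d", seq_len(fp$n_frames))
  out
}

# --- assembly -----------------------------------------------------------------

feature_class_families <- function(feature_class) {
  switch(feature_class,
    rhythmic = c("env", "imf", "tms", "wts2"),
    spectral = c("mfcc", "wts1"),
    pitch    = "f0",
    full     = c("env", "imf", "tms", "wts2", "mfcc", "wts1", "f0"),
    stop("unknown feature_class: ", feature_class))
}

# all requested families for one preprocessed clip, sharing the chunk FFT
clip_features <- function(clip, families, p) {
  out <- list()
  need_chunks <- any(c("env", "imf", "tms", "wts1", "wts2") %in% families)
  if (need_chunks) {
    ch <- chunk_signal(clip)
    X <- stats::mvfft(ch$chunks)
    if (any(c("env", "imf") %in% families)) {
      ec <- envelope_core(ch$chunks, p, X = X)
      if ("env" %in% families) out$env <- env_spectrum_from_env(ec, p)
      if ("imf" %in% families) out$imf <- imf_spectra_from_env(ec, p)
    }
    if ("tms" %in% families) out$tms <- tms_from_spectra(X, p)
    if (any(c("wts1", "wts2") %in% families)) {
      sc <- scattering_from_spectra(X, p)
      if ("wts1" %in% families) out$wts1 <- sc$wts1
      if ("wts2" %in% families) out$wts2 <- sc$wts2
    }
  }
  if ("mfcc" %in% families) out$mfcc <- mfcc_features(clip, p)
  if ("f0" %in% families) out$f0 <- f0_contour(clip, p)
  out
}

family_order <- function(feature_class) {
  # concatenation order: rhythmic block, spectral block, pitch block
  intersect(c("env", "imf", "tms", "wts2", "mfcc", "wts1", "f0"),
            feature_class_families(feature_class))
}

#' Assemble a per-sample feature matrix for one feature class
#'
#' Preprocesses every clip in the manifest (tiling to a common duration and
#' RMS) and extracts the requested feature family block:
#' `rhythmic` = \[ENV | IMF | TMS | WTS2\], `spectral` = \[MFCC | WTS1\],
#' `pitch` = \[f0\], `full` = all three concatenated.
#'
#' @param manifest A `voc_manifest` from [load_manifest()].
#' @param feature_class One of `"rhythmic"`, `"spectral"`, `"pitch"`, `"full"`.
#' @param params A [feature_params()] list.
#' @param target_duration Duration-normalization target in seconds; defaults
#'   to the maximum clip duration in the manifest.
#' @param target_rms Common RMS (see [preprocess_clip()]).
#' @param cache_dir Optional directory; assembled blocks are stored there as
#'   RDS keyed by feature class and reused when ids and settings match.
#' @param progress Print a progress note every 100 clips.
#' @return A `feature_block`: list with `matrix` (samples x dims, rownames =
#'   ids, colnames = dim names), `feature_class`, `dim_names`, `sample_ids`.
#' @export
assemble_features <- function(manifest, feature_class,
                              params = feature_params(),
                              target_duration = NULL, target_rms = 0.1,
                              cache_dir = NULL, progress = FALSE) {
  stopifnot(inherits(manifest, "voc_manifest"))
  feature_class <- match.arg(feature_class, c("rhythmic", "spectral", "pitch", "full"))
  if (is.null(target_duration)) target_duration <- max_manifest_duration(manifest)
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(cache_dir, paste0("features_", feature_class, ".rds"))
    if (file.exists(cache_file)) {
      blk <- readRDS(cache_file)
      if (identical(blk$sample_ids, manifest$id) &&
          isTRUE(all.equal(blk$target_duration, target_duration)))
        return(blk)
    }
  }
  fams <- family_order(feature_class)
  n <- nrow(manifest)
  mat <- NULL
  for (i in seq_len(n)) {
    clip <- preprocess_clip(manifest_clip(manifest, i), target_duration, target_rms)
    fv <- clip_features(clip, fams, params)
    v <- unlist(fv[fams], use.names = TRUE)
    names(v) <- sub("^[a-z0-9]+\\.", "", names(v))
    if (is.null(mat)) {
      mat <- matrix(NA_real_, n, length(v), dimnames = list(manifest$id, names(v)))
    }
    mat[i, ] <- v
    if (progress && i %% 100 == 0) message("  features: ", i, "/", n, " clips")
  }
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite feature: sample '", rownames(mat)[bad[1, 1]],
         "', dim '", colnames(mat)[bad[1, 2]], "'")
  blk <- structure(
    list(matrix = mat, feature_class = feature_class,
         dim_names = colnames(mat), sample_ids = manifest$id,
         target_duration = target_duration),
    class = "feature_block")
  if (!is.null(cache_file)) saveRDS(blk, cache_file)
  blk
}

#' Slice one feature class out of a `"full"` feature block
#'
#' The full block is the column-wise concatenation of the three families, so
#' any class block can be recovered by selecting its columns; this avoids
#' re-extracting features when several models run on one dataset.
#'
#' @param block A `feature_block` with `feature_class = "full"`.
#' @param feature_class Class to extract.
#' @return A `feature_block` of the requested class.
#' @export
subset_features <- function(block, feature_class) {
  stopifnot(inherits(block, "feature_block"))
  if (identical(feature_class, block$feature_class)) return(block)
  if (block$feature_class != "full")
    stop("can only subset a 'full' feature block")
  pattern <- c(env = "^ENV_", imf = "^IMF[12]_", tms = "^TMS_",
               wts2 = "^WTS2_", mfcc = "^MFCC_", wts1 = "^WTS1_", f0 = "^F0_")
  fams <- family_order(feature_class)
  keep <- unlist(lapply(fams, function(f)
    which(grepl(pattern[[f]], block$dim_names))))
  out <- block
  out$matrix <- block$matrix[, keep, drop = FALSE]
  out$dim_names <- block$dim_names[keep]
  out$feature_class <- feature_class
  out
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block '%s'> %d samples x %d dims\n",
              x$feature_class, nrow(x$matrix), ncol(x$matrix)), ...)
  invisible(x)
}
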