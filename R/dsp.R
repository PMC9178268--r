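# Shared signal-processing primitives. Filtering is done in the frequency
# domain on 1-s analysis bins: clips are periodic (duration-normalized by
# tiling), so circular convolution is the natural boundary handling, and the
# zero-phase Butterworth magnitude response |H|^2 equals a forward-backward
# IIR pass up to boundary effects. Band envelopes are extracted as analytic-
# signal magnitudes via windowed baseband inverse FFTs, which decimates the
# envelope for free and keeps the per-chunk cost at a handful of small FFTs.

#' Tukey (tapered cosine) window
#'
#' @param n Window length.
#' @param r Taper fraction in \[0, 1\] (0 = rectangular, 1 = Hann).
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, r = 0.1) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t >= 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / r - 2 / r + 1)))
  w
}

# zero-phase (forward-backward) Butterworth magnitude responses
butter_lp_zp <- function(f, fc, order = 4) 1 / (1 + (f / fc)^(2 * order))
butter_bp_zp <- function(f, f1, f2, order = 4) {
  w <- ifelse(f == 0, Inf, (f^2 - f1 * f2) / (f * (f2 - f1)))
  1 / (1 + w^(2 * order))
}

# equivalent rectangular bandwidth of the auditory filter at centre fc (Hz)
erb_bandwidth <- function(fc) 24.7 * (4.37 * fc / 1000 + 1)

# 4th-order gammatone magnitude response at centre fc
gammatone_mag <- function(f, fc) {
  b <- 1.019 * erb_bandwidth(fc)
  (1 + ((f - fc) / b)^2)^(-2)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank, rows = filters, cols = one-sided FFT bins
mel_filterbank <- function(n_filt, n_fft, fs) {
  n_bins <- n_fft / 2 + 1
  f_bins <- (0:(n_bins - 1)) * fs / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_filt + 2))
  fb <- matrix(0, n_filt, n_bins)
  for (i in seq_len(n_filt)) {
    lo <- edges[i]; mid <- edges[i + 1]; hi <- edges[i + 2]
    up <- (f_bins - lo) / (mid - lo)
    dn <- (hi - f_bins) / (hi - mid)
    fb[i, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II matrix rows k = 1..n_coef (DC row excluded), cols = n_in
dct_matrix <- function(n_coef, n_in) {
  k <- seq_len(n_coef)
  C <- sqrt(2 / n_in) * cos(outer(k, (seq_len(n_in) - 0.5), function(a, b) pi * a * b / n_in))
  C
}

# signed frequency (Hz) of each full-length FFT bin at 1 Hz spacing
fft_bin_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

# --- cached per-configuration plans ------------------------------------------

.voc_cache <- new.env(parent = emptyenv())

plan_key <- function(...) paste(vapply(list(...), function(x)
  paste(deparse(x), collapse = ""), character(1)), collapse = "|")

cache_get <- function(key, build) {
  if (!is.null(.voc_cache[[key]])) return(.voc_cache[[key]])
  val <- build()
  assign(key, val, envir = .voc_cache)
  val
}

# Plan for 1-s chunk processing (N = 22050, 1 Hz bin spacing).
# Holds the envelope multipliers, the gammatone bank windows for the TMS, and
# the two scattering filter banks, all on the fixed chunk FFT grid.
chunk_plan <- function(p) {
  key <- plan_key("chunk", p[c("env_band", "butter_order", "env_lowpass",
                               "tms_n_bands", "tms_range", "tms_mod_max",
                               "scat_q1", "scat_fmin", "scat_fmax", "scat_lambda2")])
  cache_get(key, function() {
    N <- voc_rate()
    f <- fft_bin_freqs(N)
    nyq <- N / 2
    # band-pass + analytic-signal multiplier (one-sided, doubled)
    analytic <- ifelse(f > 0 & f < nyq, 2, ifelse(f == 0 | f == nyq, 1, 0))
    env_bp <- butter_bp_zp(abs(f), p$env_band[1], p$env_band[2], p$butter_order) * analytic
    env_lp <- butter_lp_zp(abs(f), p$env_lowpass, p$butter_order)

    # Baseband band-envelope windows: per band, a contiguous slice of the
    # one-sided spectrum (length M_k, a power of two scaled to the band's
    # bandwidth) is inverse-FFT'd at length M_k, giving the analytic band
    # envelope decimated to M_k Hz in one small transform.
    win_len <- function(bw) {
      M <- 2^ceiling(log2(pmax(8 * bw, 1)))
      pmin(pmax(M, 512L), 4096L)
    }
    win_start <- function(fc, M)
      pmax(0L, pmin(as.integer(round(fc)) - M %/% 2L, as.integer(nyq + 1 - M)))

    # gammatone bank for the temporal modulation spectrum
    tms_fc <- exp(seq(log(p$tms_range[1]), log(p$tms_range[2]),
                      length.out = p$tms_n_bands))
    tms_bands <- lapply(tms_fc, function(fc) {
      M <- win_len(1.019 * erb_bandwidth(fc))
      s <- win_start(fc, M)
      list(fc = fc, M = M, s = s, h = gammatone_mag(s + 0:(M - 1), fc))
    })
    # per-length modulation DFT kernels, 0..tms_mod_max Hz at 1 Hz steps
    # (real/imag split so the per-chunk DFT runs through BLAS dgemm)
    mods <- 0:p$tms_mod_max
    dft_kernels <- lapply(unique(vapply(tms_bands, `[[`, 1, "M")), function(M) {
      ang <- 2 * pi * outer(mods, 0:(M - 1)) / M
      list(M = M, re = cos(ang), im = -sin(ang))
    })
    names(dft_kernels) <- vapply(dft_kernels, function(k) as.character(k$M), "")

    # first-order scattering bank: constant-Q Gaussian wavelets
    q1 <- p$scat_q1
    n1 <- floor(q1 * log2(p$scat_fmax / p$scat_fmin)) + 1
    lam1 <- p$scat_fmax * 2^(-(0:(n1 - 1)) / q1)
    sig1 <- lam1 / (q1 * 2 * sqrt(2 * log(2)))
    s1_bands <- lapply(seq_along(lam1), function(i) {
      M <- win_len(4 * sig1[i])
      s <- win_start(lam1[i], M)
      list(fc = lam1[i], M = M, s = s,
           h = exp(-(s + 0:(M - 1) - lam1[i])^2 / (2 * sig1[i]^2)))
    })

    # second-order bank acts on envelopes decimated to 512 Hz
    M2 <- 512L
    lam2 <- p$scat_lambda2
    sig2 <- lam2 / (2 * sqrt(2 * log(2)))
    f2 <- fft_bin_freqs(M2)
    s2_H <- vapply(seq_along(lam2), function(i) {
      h <- 2 * exp(-(f2 - lam2[i])^2 / (2 * sig2[i]^2))
      h[f2 <= 0] <- 0
      h
    }, numeric(M2))
    # admissible paths: modulation frequency below the parent band's bandwidth
    paths <- which(outer(lam2, lam1, function(a, b) a <= b / q1), arr.ind = TRUE)
    paths <- paths[order(paths[, 2], paths[, 1]), , drop = FALSE]

    list(N = N, M2 = M2,
         env_bp = env_bp, env_lp = env_lp, decim = p$env_decim,
         tms_fc = tms_fc, tms_bands = tms_bands, dft_kernels = dft_kernels,
         lam1 = lam1, s1_bands = s1_bands,
         lam2 = lam2, s2_H = s2_H,
         paths = paths)
  })
}

# Frame index plan for short-time analyses (MFCC / f0) on a clip of n samples
frame_plan <- function(n, win, hop) {
  key <- plan_key("frames", n, win, hop)
  cache_get(key, function() {
    n_frames <- floor((n - win) / hop) + 1
    if (n_frames < 1) stop("clip too short for ", win, "-sample frames")
    idx <- outer(seq_len(win), (seq_len(n_frames) - 1) * hop, "+")
    list(n_frames = n_frames, idx = idx)
  })
}

# analytic-signal magnitude of one frequency band for all chunk spectra at
# once: X is the full N-point FFT of every chunk (N x K), band is a
# (s, M, h) window descriptor; returns the M x K envelope matrix at M Hz
band_envelope <- function(X, band, N) {
  Xw <- X[band$s + seq_len(band$M), , drop = FALSE] * band$h
  Mod(stats::mvfft(Xw, inverse = TRUE)) * (2 / N)
}
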