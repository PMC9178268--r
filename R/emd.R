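# Empirical mode decomposition of amplitude envelopes. Classical sifting:
# cubic-spline upper/lower envelopes through local extrema (endpoints
# anchored as knots), stopping a sift when the Cauchy-style criterion
# sum((h_prev - h)^2) / sum(h_prev^2) drops below a threshold.

local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse plateaus so sign changes are detected across them
  nz <- s != 0
  if (!any(nz)) return(list(max = integer(0), min = integer(0)))
  idx <- which(nz)
  ch <- which(diff(s[idx]) != 0)
  turn <- idx[ch] + 1L
  kind <- s[idx][ch]  # +1 -> rising before turn: maximum
  list(max = turn[kind > 0], min = turn[kind < 0])
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) plus a residue by
#' iterative sifting. IMF1 carries the fastest oscillation present; for 1-s
#' vocal amplitude envelopes this is the syllabic-rate component, with IMF2
#' the supra-syllabic component. The decomposition is exactly additive:
#' `rowSums(imfs) + residue` reproduces the input to numerical precision.
#'
#' @param x Numeric series (an amplitude envelope).
#' @param max_imf Maximum number of IMFs to extract (default 6).
#' @param sift_max Maximum sifting iterations per IMF (default 10).
#' @param sd_thresh Cauchy stopping threshold for sifting (default 0.2).
#' @return List with `imfs` (length(x) x k matrix, possibly 0 columns) and
#'   `residue`.
#' @export
emd <- function(x, max_imf = 6, sift_max = 10, sd_thresh = 0.2) {
  n <- length(x)
  t <- seq_len(n)
  imfs <- matrix(0, n, 0)
  r <- x
  for (k in seq_len(max_imf)) {
    ex <- local_extrema(r)
    if (length(ex$max) < 1 || length(ex$min) < 1) break
    h <- r
    for (s in seq_len(sift_max)) {
      ex_h <- local_extrema(h)
      if (length(ex_h$max) < 1 || length(ex_h$min) < 1) break
      ku <- unique(c(1L, ex_h$max, n))
      kl <- unique(c(1L, ex_h$min, n))
      upper <- stats::spline(ku, h[ku], xout = t, method = "natural")$y
      lower <- stats::spline(kl, h[kl], xout = t, method = "natural")$y
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_k <- sum((h - h_new)^2) / (sum(h^2) + 1e-300)
      h <- h_new
      if (sd_k < sd_thresh) break
    }
    imfs <- cbind(imfs, h)
    r <- r - h
  }
  colnames(imfs) <- if (ncol(imfs)) paste0("IMF", seq_len(ncol(imfs)))
  list(imfs = imfs, residue = r)
}
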