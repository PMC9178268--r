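# Synthetic vocalization generator. Clips are controlled acoustic stand-ins,
# not naturalistic calls: a harmonic source with a slowly sweeping f0, shaped
# by Gaussian spectral resonances, amplitude-modulated by a jittered
# raised-cosine syllable train, plus white noise. The three class-separation
# axes (syllable rate, resonances, f0) map one-to-one onto the three feature
# families, so presets that separate classes along a single axis let each
# feature family's discriminative power be measured in isolation.

#' Specification of one synthetic vocalization type
#'
#' @param type_name Type label.
#' @param class_label `"+cognition"` or `"-cognition"`.
#' @param syllable_rate Mean syllable rate in Hz (must lie in 1--10 Hz, inside
#'   the envelope/TMS analysis band).
#' @param rate_jitter Inter-pulse-interval jitter SD as a fraction of the
#'   syllable period (default 0.1).
#' @param syllable_shape Raised-cosine pulse width as a fraction of the
#'   syllable period, in (0, 1).
#' @param resonances List of `c(center_hz, bandwidth_hz, gain_db)` triplets
#'   shaping the spectral envelope.
#' @param f0_base Base fundamental frequency (Hz).
#' @param f0_excursion Pitch contour depth in semitones.
#' @param f0_contour_rate Rate of the sinusoidal pitch contour (Hz).
#' @param am_floor Amplitude floor of the syllable train, as a fraction of the
#'   pulse peak (default 0.2). A non-zero floor keeps the harmonic source
#'   audible between syllables, so the pitch track does not time-encode the
#'   syllable rhythm.
#' @param harmonic_count Number of harmonic partials of the source.
#' @param rumble_level Level of a syllable-modulated low-frequency noise band
#'   (80--450 Hz, glottal/breath rumble), as a fraction of the harmonic
#'   source RMS (default 0). When shared by every type it partially masks the
#'   fundamental-frequency region of auditory-band features, at the cost of
#'   occasional pitch-tracker distraction.
#' @param noise_snr Additive white-noise level, dB SNR re the harmonic part.
#' @param duration_mean,duration_sigma Lognormal clip-duration distribution:
#'   mean in seconds and log-scale SD. Durations are truncated to
#'   \[0.5, 9.54\] s so the duration-normalization target stays bounded.
#' @param f0_clip_jitter Per-clip f0 jitter SD in semitones (default 0):
#'   within-type talker/utterance variability.
#' @param rate_clip_jitter Per-clip multiplicative syllable-rate jitter SD
#'   (default 0).
#' @param res_clip_jitter Per-clip multiplicative resonance-centre jitter SD
#'   (default 0).
#' @param tilt_clip_jitter Per-clip spectral-tilt jitter SD in dB/octave
#'   (default 0).
#' @param shape_clip_jitter Per-clip syllable-width jitter SD (default 0;
#'   width clamped to \[0.2, 0.9\]).
#' @param floor_clip_jitter Per-clip AM-floor jitter SD (default 0; floor
#'   clamped to \[0.05, 0.45\]).
#' @param snr_clip_jitter Per-clip SNR jitter SD in dB (default 0): recording
#'   conditions vary from clip to clip.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(type_name, class_label,
                       syllable_rate = 5, rate_jitter = 0.1,
                       syllable_shape = 0.6, am_floor = 0.2,
                       resonances = list(c(800, 200, 10), c(2200, 400, 8)),
                       f0_base = 300, f0_excursion = 2, f0_contour_rate = 1.5,
                       harmonic_count = 12, rumble_level = 0, noise_snr = 20,
                       duration_mean = 2, duration_sigma = 0.5,
                       f0_clip_jitter = 0, rate_clip_jitter = 0,
                       res_clip_jitter = 0, tilt_clip_jitter = 0,
                       shape_clip_jitter = 0, floor_clip_jitter = 0,
                       snr_clip_jitter = 0) {
  s <- as.list(environment())
  s$class_label <- normalize_class_label(class_label)
  if (syllable_rate < 1 || syllable_rate > 10)
    stop("syllable_rate must be within 1-10 Hz")
  if (syllable_shape <= 0 || syllable_shape >= 1)
    stop("syllable_shape must be in (0, 1)")
  if (f0_base < 50 || f0_base > 1000)
    stop("f0_base must lie within the pitch extractor's range (50-1000 Hz)")
  if (any(vapply(resonances, function(r) r[1], 1) >= voc_rate() / 2))
    stop("resonance centers must be below the Nyquist frequency")
  class(s) <- "synth_spec"
  s
}

#' Generate one synthetic vocalization clip
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; the same spec and seed yield an identical clip.
#' @param id Clip id.
#' @return An `audio_clip` at 22,050 Hz, peak-normalized.
#' @export
generate_clip <- function(spec, seed, id = spec$type_name) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- voc_rate()
  set.seed(as.integer(seed))
  mu <- log(spec$duration_mean) - spec$duration_sigma^2 / 2
  dur <- min(9.54, max(0.5, exp(stats::rnorm(1, mu, spec$duration_sigma))))
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs

  # per-clip (within-type) parameter variability, truncated at 2 SD
  jit <- function(sd) max(-2 * sd, min(2 * sd, stats::rnorm(1, 0, sd)))
  f0_base <- spec$f0_base * 2^(jit(spec$f0_clip_jitter) / 12)
  syl_rate <- spec$syllable_rate * (1 + jit(spec$rate_clip_jitter))
  res <- lapply(spec$resonances, function(r)
    c(r[1] * (1 + jit(spec$res_clip_jitter)), r[2], r[3]))
  tilt <- jit(spec$tilt_clip_jitter)  # dB per octave re 1 kHz
  shape <- min(0.9, max(0.2, spec$syllable_shape + jit(spec$shape_clip_jitter)))
  floor_amp <- min(0.45, max(0.05, spec$am_floor + jit(spec$floor_clip_jitter)))

  # harmonic source with sinusoidal pitch contour
  phi0 <- stats::runif(1, 0, 2 * pi)
  f0 <- f0_base * 2^((spec$f0_excursion / 12) *
                     sin(2 * pi * spec$f0_contour_rate * t + phi0))
  phase <- 2 * pi * cumsum(f0) / fs
  res_gain_db <- function(f) {
    g <- tilt * log2(f / 1000)
    for (r in res) g <- g + r[3] * exp(-(f - r[1])^2 / (2 * r[2]^2))
    g
  }
  src <- numeric(n)
  for (h in seq_len(spec$harmonic_count)) {
    fh <- h * f0_base
    if (fh >= 0.45 * fs) break
    src <- src + (10^(res_gain_db(fh) / 20) / h) * sin(h * phase)
  }

  # jittered raised-cosine syllable train on a non-zero floor
  period <- 1 / syl_rate
  onsets <- seq(0, dur, by = period)
  onsets <- onsets + stats::rnorm(length(onsets), 0, spec$rate_jitter * period)
  width <- shape * period
  env <- rep(floor_amp, n)
  for (on in onsets) {
    i0 <- max(1, floor(on * fs) + 1)
    i1 <- min(n, floor((on + width) * fs) + 1)
    if (i1 <= i0) next
    u <- (t[i0:i1] - on) / width
    env[i0:i1] <- env[i0:i1] + 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))
  }
  if (spec$rumble_level > 0) {
    bp <- signal::butter(2, c(80, 450) / (fs / 2), "pass")
    rumble <- as.numeric(signal::filter(bp, stats::rnorm(n)))
    rumble <- rumble * spec$rumble_level * rms(src) / max(rms(rumble), 1e-12)
    src <- src + rumble
  }
  x <- src * env
  sig_rms <- rms(x)
  if (sig_rms > 0) {
    snr <- spec$noise_snr + jit(spec$snr_clip_jitter)
    noise_sd <- sig_rms * 10^(-snr / 20)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  x <- 0.95 * x / max(abs(x))
  audio_clip(id, x, fs, spec$type_name, spec$class_label)
}

#' Built-in dataset presets
#'
#' Five vocalization types (three `+cognition`, two `-cognition`) whose
#' generative parameters differ across classes along controlled axes:
#' \describe{
#'   \item{rhythm_only}{classes differ only in syllable rate
#'     (4.0/4.5/5.0 Hz vs 7.5/8.5 Hz);}
#'   \item{spectral_only}{only in resonance (formant-like) structure,
#'     low-frequency vs high-frequency resonances;}
#'   \item{pitch_only}{only in f0 (220/240/260 Hz vs 330/370 Hz);}
#'   \item{full}{all three axes separated, with per-type duration means
#'     echoing a field dataset (1.2--9.5 s);}
#'   \item{null}{all five types share one spec, so the classes are
#'     statistically identical.}
#' }
#'
#' @param name Preset name.
#' @param n_per_type Clips generated per type.
#' @param seed Master seed for dataset generation.
#' @return A list of class `dataset_preset` with fields `name`, `specs`
#'   (five `synth_spec`s), `n_per_type`, `seed`.
#' @export
dataset_preset <- function(name = c("rhythm_only", "spectral_only",
                                    "pitch_only", "full", "null"),
                           n_per_type = 100, seed = 1) {
  name <- match.arg(name)
  plus_rates <- c(4.0, 4.5, 5.0); minus_rates <- c(7.5, 8.5)
  plus_res <- list(
    list(c(500, 150, 12), c(1500, 250, 10)),
    list(c(700, 180, 12), c(1800, 300, 10)),
    list(c(600, 160, 12), c(1650, 280, 10)))
  minus_res <- list(
    list(c(2600, 350, 12), c(3600, 400, 10)),
    list(c(2900, 380, 12), c(3900, 420, 10)))
  plus_f0 <- c(220, 240, 260); minus_f0 <- c(330, 370)
  full_dur_plus <- c(1.23, 2.62, 1.55); full_dur_minus <- c(1.94, 9.54)

  types_plus <- paste0("plus_", 1:3)
  types_minus <- paste0("minus_", 1:2)
  mk <- function(i, cls) {
    type <- if (cls == "+cognition") types_plus[i] else types_minus[i]
    # within-type per-clip variability shared by every preset: realistic
    # talker/utterance spread, and it keeps any single acoustic axis from
    # being read off perfectly through a correlated feature family
    args <- list(type_name = type, class_label = cls,
                 harmonic_count = 40, f0_excursion = 4, f0_contour_rate = 2.5,
                 f0_clip_jitter = 1.5, rate_clip_jitter = 0.02,
                 res_clip_jitter = 0.10, tilt_clip_jitter = 1.5,
                 shape_clip_jitter = 0.10, floor_clip_jitter = 0.07,
                 am_floor = 0.25)
    if (name %in% c("rhythm_only", "full"))
      args$syllable_rate <- if (cls == "+cognition") plus_rates[i] else minus_rates[i]
    if (name %in% c("spectral_only", "full"))
      args$resonances <- if (cls == "+cognition") plus_res[[i]] else minus_res[[i]]
    if (name %in% c("pitch_only", "full"))
      args$f0_base <- if (cls == "+cognition") plus_f0[i] else minus_f0[i]
    if (name == "full") {
      args$duration_mean <- if (cls == "+cognition") full_dur_plus[i] else full_dur_minus[i]
    }
    do.call(synth_spec, args)
  }
  specs <- c(lapply(1:3, mk, cls = "+cognition"),
             lapply(1:2, mk, cls = "-cognition"))
  structure(list(name = name, specs = specs,
                 n_per_type = n_per_type, seed = as.integer(seed)),
            class = "dataset_preset")
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_per_type` PCM-16 WAV clips per type plus a manifest CSV in the
#' dialect read by [load_manifest()]. Generation is reproducible: identical
#' preset and seed yield byte-identical files.
#'
#' @param preset A [dataset_preset()].
#' @param out_dir Output directory (created if needed).
#' @return The loaded `voc_manifest` for the generated dataset, invisibly.
#' @export
generate_dataset <- function(preset, out_dir) {
  stopifnot(inherits(preset, "dataset_preset"), preset$n_per_type >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0L
  for (s in preset$specs) {
    for (j in seq_len(preset$n_per_type)) {
      k <- k + 1L
      id <- sprintf("%s_%03d", s$type_name, j)
      clip <- generate_clip(s, seed = child_seed(preset$seed, k), id = id)
      fn <- paste0(id, ".wav")
      write_wav(clip$waveform, clip$sample_rate, file.path(out_dir, fn))
      rows[[k]] <- data.frame(id = id, path = fn, voc_type = s$type_name,
                              class_label = s$class_label,
                              stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(load_manifest(file.path(out_dir, "manifest.csv")))
}
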