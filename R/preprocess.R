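# Preprocessing: manifest handling, intensity/duration normalization, chunking.
# All downstream feature extractors assume the contract established here:
# mono, 22,050 Hz, common RMS, duration equalized by periodic tiling, analyzed
# in consecutive non-overlapping 1-s bins.

#' Processing sample rate (Hz) shared by the whole pipeline
#' @export
voc_rate <- function() 22050L

#' Construct an audio clip object
#'
#' @param id Sample identifier.
#' @param waveform Numeric amplitude vector (dimensionless).
#' @param sample_rate Sampling rate in Hz.
#' @param voc_type Vocalization type label.
#' @param class_label Binary class label, `"+cognition"` or `"-cognition"`.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(id, waveform, sample_rate,
                       voc_type = NA_character_, class_label = NA_character_) {
  waveform <- as.numeric(waveform)
  if (length(waveform) == 0 || !all(is.finite(waveform)))
    stop("clip '", id, "': waveform must be finite and non-empty")
  structure(
    list(id = as.character(id), waveform = waveform,
         sample_rate = as.numeric(sample_rate),
         voc_type = as.character(voc_type),
         class_label = as.character(class_label)),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s'> %.3f s @ %g Hz, type=%s, class=%s\n",
              x$id, length(x$waveform) / x$sample_rate, x$sample_rate,
              x$voc_type, x$class_label), ...)
  invisible(x)
}

#' Duration of a clip in seconds
#' @param clip An `audio_clip`.
#' @export
clip_duration <- function(clip) length(clip$waveform) / clip$sample_rate

rms <- function(x) sqrt(mean(x^2))

#' Load and validate a dataset manifest
#'
#' The manifest is a CSV with header `id,path,voc_type,class_label`, one row
#' per clip. Class labels must be `+cognition` / `-cognition` (a leading
#' Unicode minus is accepted). Every vocalization type must map to exactly one
#' class, and ids must be unique.
#'
#' @param path Path to the manifest CSV. WAV paths are interpreted relative to
#'   the manifest's directory when not absolute.
#' @param check_files Verify that every WAV file exists (default `TRUE`).
#' @return A `data.frame` of class `voc_manifest` with columns
#'   `id`, `path`, `voc_type`, `class_label`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "path", "voc_type", "class_label")
  if (!all(required %in% names(m)))
    stop("manifest must have columns ", paste(required, collapse = ","))
  m <- m[, required]
  m$class_label <- normalize_class_label(m$class_label)
  if (anyDuplicated(m$id))
    stop("duplicate manifest ids: ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  bad <- tapply(m$class_label, m$voc_type, function(z) length(unique(z)) > 1)
  if (any(bad))
    stop("voc_type mapped to both classes: ",
         paste(names(bad)[bad], collapse = ", "))
  root <- dirname(normalizePath(path))
  abs <- grepl("^(/|[A-Za-z]:)", m$path)
  m$path[!abs] <- file.path(root, m$path[!abs])
  if (check_files) {
    missing <- !file.exists(m$path)
    if (any(missing))
      stop("missing WAV files: ", paste(m$path[missing], collapse = ", "))
  }
  class(m) <- c("voc_manifest", "data.frame")
  m
}

normalize_class_label <- function(x) {
  x <- gsub("−", "-", trimws(x))
  ok <- x %in% c("+cognition", "-cognition")
  if (!all(ok))
    stop("class_label must be '+cognition' or '-cognition'; got: ",
         paste(unique(x[!ok]), collapse = ", "))
  x
}

#' Read the clip behind one manifest row
#'
#' @param manifest A `voc_manifest`.
#' @param i Row index or id.
#' @return An `audio_clip` (raw, not yet preprocessed).
#' @export
manifest_clip <- function(manifest, i) {
  if (is.character(i)) i <- match(i, manifest$id)
  row <- manifest[i, ]
  w <- read_wav(row$path)
  audio_clip(row$id, w$samples, w$sample_rate, row$voc_type, row$class_label)
}

#' Normalize a clip's intensity, rate, and duration
#'
#' Resamples to 22,050 Hz (polyphase), extends the clip to `target_duration`
#' by periodic tiling (tile-then-truncate), and scales the result to a common
#' RMS. With intensity equalized, clips are comparable regardless of original
#' recording gain; with duration equalized, every feature family yields a
#' fixed-length vector per clip.
#'
#' @param clip An `audio_clip`.
#' @param target_duration Target duration in seconds. The analysis drivers pin
#'   the dataset-wide maximum here (see [max_manifest_duration()]).
#' @param target_rms Common RMS amplitude after normalization (default 0.1,
#'   i.e. -20 dBFS; only its being shared across clips matters downstream).
#' @return The preprocessed `audio_clip` (22,050 Hz).
#' @export
preprocess_clip <- function(clip, target_duration, target_rms = 0.1) {
  stopifnot(inherits(clip, "audio_clip"), target_duration > 0, target_rms > 0)
  x <- clip$waveform
  if (rms(x) == 0) stop("clip '", clip$id, "' is silent (RMS = 0)")
  fs <- voc_rate()
  if (clip$sample_rate != fs) {
    frac <- rational_approx(fs / clip$sample_rate)
    x <- as.numeric(signal::resample(x, frac[1], frac[2]))
  }
  n_target <- round(target_duration * fs)
  if (n_target < 1) stop("target_duration too short")
  reps <- ceiling(n_target / length(x))
  x <- rep.int(x, reps)[seq_len(n_target)]
  x <- x * (target_rms / rms(x))
  audio_clip(clip$id, x, fs, clip$voc_type, clip$class_label)
}

rational_approx <- function(r, max_den = 1000L) {
  # best rational p/q approximation by continued fractions
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x <- r
  repeat {
    a <- floor(x)
    p2 <- as.integer(a * p1 + p0); q2 <- as.integer(a * q1 + q0)
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(p1, q1)
}

#' Maximum clip duration across a manifest (seconds)
#'
#' Used as the default duration-normalization target: every clip is tiled up
#' to the longest clip in the dataset.
#'
#' @param manifest A `voc_manifest`.
#' @export
max_manifest_duration <- function(manifest) {
  max(vapply(seq_len(nrow(manifest)), function(i) {
    w <- read_wav(manifest$path[i])
    length(w$samples) / w$sample_rate
  }, numeric(1)))
}

#' Cut a preprocessed clip into consecutive 1-s analysis bins
#'
#' @param clip A preprocessed `audio_clip` at 22,050 Hz.
#' @param bin_seconds Bin length in seconds (default 1).
#' @return A `chunked_signal`: list with `chunks` (samples x n_chunks matrix)
#'   and `source_id`. A trailing partial bin is discarded.
#' @export
chunk_signal <- function(clip, bin_seconds = 1.0) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate != voc_rate())
    stop("clip must be preprocessed to ", voc_rate(), " Hz")
  n_bin <- round(bin_seconds * clip$sample_rate)
  n_chunks <- floor(length(clip$waveform) / n_bin)
  if (n_chunks < 1)
    stop("clip '", clip$id, "' shorter than one ", bin_seconds, "-s bin")
  structure(
    list(chunks = matrix(clip$waveform[seq_len(n_chunks * n_bin)], nrow = n_bin),
         source_id = clip$id),
    class = "chunked_signal")
}
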