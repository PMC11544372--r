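# Energy-based voiced-segment detection and phonation time.
#
# Two-step detector: (1) split the waveform into candidate segments wherever
# frame energy rises above peak-minus-top_db; (2) keep a candidate as voiced
# when its RMS energy exceeds an amplitude threshold derived from the 0.99
# amplitude quantile lowered by 25 dB. Both steps scale with the waveform,
# so phonation time is invariant under amplitude rescaling.

#' Detector configuration
#'
#' @param split_top_db Maximum allowed drop (dB) below the peak frame energy
#'   for a frame to belong to a candidate segment. Default 20.
#' @param voiced_floor_db Level (dB) below the robust amplitude peak at which
#'   the voiced/unvoiced threshold is set. Default -25.
#' @param amplitude_quantile Quantile of `|samples|` used as the robust peak.
#'   Default 0.99.
#' @param frame_length,hop_length Analysis frame and hop in samples
#'   (defaults 2048 and 512; about 46 ms / 12 ms at 44.1 kHz).
#' @return An object of class `phonation_config`.
#' @export
phonation_config <- function(split_top_db = 20, voiced_floor_db = -25,
                             amplitude_quantile = 0.99,
                             frame_length = 2048L, hop_length = 512L) {
  if (split_top_db <= 0) stop_config("split_top_db must be positive")
  if (amplitude_quantile <= 0 || amplitude_quantile >= 1) {
    stop_config("amplitude_quantile must lie strictly in (0, 1)")
  }
  if (hop_length <= 0 || frame_length < hop_length) {
    stop_config("need frame_length >= hop_length > 0")
  }
  structure(list(split_top_db = split_top_db,
                 voiced_floor_db = voiced_floor_db,
                 amplitude_quantile = amplitude_quantile,
                 frame_length = as.integer(frame_length),
                 hop_length = as.integer(hop_length)),
            class = "phonation_config")
}

# Per-frame RMS over non-centred frames; short final frames are kept.
frame_rms <- function(samples, frame_length, hop_length) {
  n <- length(samples)
  if (n == 0L) return(numeric(0))
  starts <- seq(1L, max(1L, n - hop_length + 1L), by = hop_length)
  vapply(starts, function(s) {
    e <- min(n, s + frame_length - 1L)
    sqrt(mean(samples[s:e]^2))
  }, numeric(1))
}

#' Candidate voiced segments from frame energy
#'
#' Returns the maximal runs of frames whose energy stays within
#' `split_top_db` of the peak frame energy, as time intervals.
#'
#' @param wav A [waveform()].
#' @param config A [phonation_config()].
#' @return Tibble with columns `start`, `end` (seconds), ordered and
#'   non-overlapping; empty for an all-silent (zero) input.
#' @export
split_candidates <- function(wav, config = phonation_config()) {
  if (length(wav$samples) == 0L) stop_config("empty waveform")
  rms <- frame_rms(wav$samples, config$frame_length, config$hop_length)
  peak <- max(rms)
  if (peak == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  db <- 20 * log10(pmax(rms, .Machine$double.xmin) / peak)
  keep <- db > -config$split_top_db
  if (!any(keep)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vi <- which(r$values)
  dur <- length(wav$samples) / wav$rate
  tibble::tibble(
    start = (starts[vi] - 1L) * config$hop_length / wav$rate,
    end = pmin(dur, ((ends[vi] - 1L) * config$hop_length +
                       config$frame_length) / wav$rate)
  )
}

#' Amplitude threshold separating voiced from unvoiced candidates
#'
#' The threshold combines a decibel floor with a robust amplitude peak:
#' `quantile(|x|, amplitude_quantile) * 10^(voiced_floor_db / 20)`, i.e. by
#' default 25 dB below the 0.99 amplitude quantile. It scales linearly with
#' the waveform, keeping the detector amplitude-invariant.
#'
#' @inheritParams split_candidates
#' @return Amplitude threshold (same units as the samples).
#' @export
voiced_threshold <- function(wav, config = phonation_config()) {
  if (length(wav$samples) == 0L) stop_config("empty waveform")
  q <- stats::quantile(abs(wav$samples), config$amplitude_quantile,
                       names = FALSE, type = 7)
  q * 10^(config$voiced_floor_db / 20)
}

#' Phonation time of a waveform
#'
#' Sum of the durations of candidate segments whose mean frame RMS exceeds
#' the voiced threshold. Bounded by the waveform duration.
#'
#' @inheritParams split_candidates
#' @return Phonation time in seconds (0 for silence).
#' @export
#' @examples
#' w <- generate_waveform(data.frame(duration = c(0.5, 0.4, 0.5),
#'                                   voiced = c(TRUE, FALSE, TRUE)))
#' phonation_time(w)  # close to 1.0
phonation_time <- function(wav, config = phonation_config()) {
  segs <- split_candidates(wav, config)
  if (nrow(segs) == 0L) return(0)
  thr <- voiced_threshold(wav, config)
  dur <- 0
  for (i in seq_len(nrow(segs))) {
    a <- max(1L, floor(segs$start[i] * wav$rate) + 1L)
    b <- min(length(wav$samples), ceiling(segs$end[i] * wav$rate))
    rms <- frame_rms(wav$samples[a:b], config$frame_length, config$hop_length)
    if (mean(rms) > thr) dur <- dur + (segs$end[i] - segs$start[i])
  }
  min(dur, waveform_duration(wav))
}

#' Phonation time for each phrase of a recording
#'
#' Slices the recording waveform at each phrase's onset/offset and runs the
#' detector on the slice, so silence at phrase edges reduces phonation time
#' but never the syllable count.
#'
#' @param wav Recording [waveform()].
#' @param phrases Phrase tibble with `onset` and `offset` (seconds).
#' @param config A [phonation_config()].
#' @return `phrases` with a `phonation_time` column added; zero-phonation
#'   phrases are flagged in `rate_eligible` (created if absent).
#' @export
add_phonation_times <- function(wav, phrases, config = phonation_config()) {
  pt <- vapply(seq_len(nrow(phrases)), function(i) {
    a <- max(1L, floor(phrases$onset[i] * wav$rate) + 1L)
    b <- min(length(wav$samples), ceiling(phrases$offset[i] * wav$rate))
    if (b < a) return(0)
    phonation_time(waveform(wav$samples[a:b], wav$rate), config)
  }, numeric(1))
  phrases$phonation_time <- pt
  elig <- (phrases[["rate_eligible"]] %||% TRUE) & pt > 0
  if (any(pt == 0)) {
    message(sum(pt == 0),
            " phrase(s) have zero detected phonation; excluded from rate analyses")
  }
  phrases$rate_eligible <- elig
  phrases
}
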