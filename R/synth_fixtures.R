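#' Construct a waveform object
#'
#' A waveform is a mono amplitude sequence in \[-1, 1\] with a sample rate
#' and, for synthetic fixtures, an optional table of ground-truth
#' voiced/silent segments tiling the full duration.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param rate Samples per second (> 0).
#' @param truth_segments Optional tibble with columns `start`, `end`
#'   (seconds) and `voiced` (logical).
#' @return An object of class `regspeech_waveform`.
#' @export
waveform <- function(samples, rate, truth_segments = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_config("sample rate must be a positive number")
  }
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stop_config("waveform amplitudes must lie in [-1, 1]")
  }
  structure(list(samples = as.numeric(samples), rate = rate,
                 truth_segments = truth_segments),
            class = "regspeech_waveform")
}

#' @exportS3Method base::print
print.regspeech_waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.3f s at %g Hz%s>\n",
              length(x$samples) / x$rate, x$rate,
              if (!is.null(x$truth_segments)) {
                sprintf(", %d truth segments", nrow(x$truth_segments))
              } else {
                ""
              }))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wav A [waveform()].
#' @return Length of the waveform in seconds.
#' @export
waveform_duration <- function(wav) {
  length(wav$samples) / wav$rate
}

#' Synthesize a waveform with a known voiced/silent layout
#'
#' Builds an audio fixture for the phonation detector: voiced spans are
#' band-limited harmonic tones (fundamental plus two harmonics, with short
#' onset/offset ramps), silent spans are near-zero noise. The returned
#' `truth_segments` reproduce the requested layout exactly, so detected
#' phonation time can be scored against truth.
#'
#' @param layout Data frame with columns `duration` (seconds, > 0), `voiced`
#'   (logical) and optionally `amplitude` (peak amplitude; defaults 0.5 for
#'   voiced and 1e-4 for silent spans). Voiced amplitudes must be at least
#'   ten times the largest silent amplitude.
#' @param rate Sample rate in Hz (default 44100).
#' @param f0 Fundamental of the voiced tone, Hz.
#' @param seed Optional seed for the silence noise.
#' @return A [waveform()] whose `truth_segments` tile the full duration.
#' @export
#' @examples
#' w <- generate_waveform(data.frame(duration = c(0.5, 0.4, 0.5),
#'                                   voiced = c(TRUE, FALSE, TRUE)))
#' sum(with(w$truth_segments, (end - start)[voiced]))
generate_waveform <- function(layout, rate = 44100, f0 = 220, seed = NULL) {
  layout <- as.data.frame(layout)
  if (nrow(layout) == 0L) {
    stop_config("waveform layout must contain at least one span")
  }
  if (!all(c("duration", "voiced") %in% names(layout))) {
    stop_config("layout needs columns 'duration' and 'voiced'")
  }
  if (any(layout$duration <= 0)) {
    stop_config("layout durations must be positive")
  }
  if (is.null(layout$amplitude)) {
    layout$amplitude <- ifelse(layout$voiced, 0.5, 1e-4)
  }
  sil_amp <- layout$amplitude[!layout$voiced]
  if (any(layout$voiced) && length(sil_amp) &&
      min(layout$amplitude[layout$voiced]) < 10 * max(sil_amp)) {
    stop_config("voiced amplitudes must be >= 10x the silence amplitude")
  }
  with_seed(seed, {
    n_span <- pmax(1L, round(layout$duration * rate))
    pieces <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      n <- n_span[i]
      if (layout$voiced[i]) {
        t <- seq_len(n) / rate
        x <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t) +
          0.25 * sin(2 * pi * 3 * f0 * t)
        x <- x / max(abs(x)) * layout$amplitude[i]
        ramp <- min(n %/% 2, round(0.005 * rate))
        if (ramp > 0) {
          w <- seq_len(ramp) / ramp
          x[seq_len(ramp)] <- x[seq_len(ramp)] * w
          x[n - ramp + seq_len(ramp)] <- x[n - ramp + seq_len(ramp)] * rev(w)
        }
        pieces[[i]] <- x
      } else {
        pieces[[i]] <- stats::runif(n, -1, 1) * layout$amplitude[i]
      }
    }
    bounds <- cumsum(c(0L, n_span)) / rate
    waveform(unlist(pieces), rate,
             truth_segments = tibble::tibble(
               start = bounds[-length(bounds)],
               end = bounds[-1],
               voiced = layout$voiced
             ))
  })
}

#' Build a word tier from explicit durations and gaps
#'
#' Low-level fixture constructor: lays words on a timeline with the exact
#' inter-word gaps requested, so segmentation behaviour at and around the
#' pause threshold can be tested against hand-enumerated expectations.
#'
#' @param durations Word durations in seconds (> 0).
#' @param gaps_before Gap preceding each word in seconds (same length;
#'   `gaps_before[1]` is silence before the first word).
#' @param labels Optional word labels.
#' @return A word-tier tibble with columns `label`, `start`, `end`.
#' @export
#' @examples
#' word_tier_from_layout(c(1, 1), gaps_before = c(0, 0.6))
word_tier_from_layout <- function(durations, gaps_before,
                                  labels = paste0("w", seq_along(durations))) {
  stopifnot(length(durations) == length(gaps_before),
            all(durations > 0), all(gaps_before >= 0))
  end <- cumsum(durations + gaps_before)
  tibble::tibble(label = labels, start = end - durations, end = end)
}

#' Generate word and phone alignment tiers for a set of phrases
#'
#' Emulates forced-aligner output for one recording: each phrase is split
#' into words separated by small within-phrase gaps (below the pause
#' threshold), and each word into consonant/vowel phone pairs, with exactly
#' the phrase's number of syllables realized as flagged vowel phones. Gaps
#' between phrases follow directly from the phrase onsets/offsets.
#'
#' @param phrases Tibble for a single recording with columns `onset`,
#'   `offset`, `n_syllables` (non-overlapping, time-ordered).
#' @param words_per_phrase Target words per phrase; capped at the phrase's
#'   syllable count (a zero-syllable phrase becomes one consonant-only word).
#' @param gap_within Within-phrase inter-word gap in seconds; must stay below
#'   the segmentation pause threshold to keep phrases intact.
#' @param vowel_categories Labels assigned to the vowel phones.
#' @param seed Optional seed for vowel-category sampling.
#' @return List with `words` (tibble `label`, `start`, `end`) and `phones`
#'   (tibble `label`, `start`, `end`, `is_target_vowel`, `vowel_category`,
#'   `parent_word`).
#' @export
generate_alignment <- function(phrases, words_per_phrase = 3,
                               gap_within = 0.05,
                               vowel_categories = vowel_inventory()$categories,
                               seed = NULL) {
  phrases <- phrases[order(phrases$onset), , drop = FALSE]
  if (nrow(phrases) > 1 &&
      any(phrases$onset[-1] < phrases$offset[-nrow(phrases)])) {
    stop_config("phrases overlap in time: invalid layout")
  }
  with_seed(seed, {
    words <- list()
    phones <- list()
    widx <- 0L
    for (i in seq_len(nrow(phrases))) {
      p <- phrases[i, ]
      ns <- p$n_syllables
      nw <- if (ns == 0) 1L else max(1L, min(words_per_phrase, ns))
      span <- p$offset - p$onset
      wdur <- (span - (nw - 1) * gap_within) / nw
      if (wdur <= 0) {
        stop_config("phrase %d too short for %d words with gap %g s",
                    i, nw, gap_within)
      }
      syl_per_word <- rep(ns %/% nw, nw) +
        c(rep(1L, ns %% nw), rep(0L, nw - ns %% nw))
      for (w in seq_len(nw)) {
        widx <- widx + 1L
        wstart <- p$onset + (w - 1) * (wdur + gap_within)
        wend <- wstart + wdur
        words[[widx]] <- tibble::tibble(
          label = sprintf("w%03d", widx), start = wstart, end = wend)
        nsw <- syl_per_word[w]
        if (nsw == 0L) {
          phones[[length(phones) + 1L]] <- tibble::tibble(
            label = "s", start = wstart, end = wend,
            is_target_vowel = FALSE, vowel_category = NA_character_,
            parent_word = widx)
        } else {
          # each syllable is one consonant phone followed by one vowel phone
          edges <- seq(wstart, wend, length.out = 2L * nsw + 1L)
          cats <- sample(vowel_categories, nsw, replace = TRUE)
          for (s in seq_len(nsw)) {
            phones[[length(phones) + 1L]] <- tibble::tibble(
              label = c("t", cats[s]),
              start = edges[c(2 * s - 1, 2 * s)],
              end = edges[c(2 * s, 2 * s + 1)],
              is_target_vowel = c(FALSE, TRUE),
              vowel_category = c(NA_character_, cats[s]),
              parent_word = widx)
          }
        }
      }
    }
    list(words = dplyr::bind_rows(words), phones = dplyr::bind_rows(phones))
  })
}
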