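# Phrase segmentation from the word tier.

#' Build phrases from a word tier by the pause rule
#'
#' A phrase is a maximal run of consecutive words in which every inter-word
#' pause is shorter than `gap_threshold`; a pause that reaches or exceeds
#' the threshold starts a new phrase. Phrase onset/offset are the first
#' word's start and the last word's end. The default threshold is 500 ms.
#'
#' Gaps are computed from word-tier timestamps only. A gap equal to the
#' threshold splits (ties split); comparison uses a 1 ns guard against
#' floating-point representation of the timestamps.
#'
#' @param words Word-tier tibble (`label`, `start`, `end`), time-ordered and
#'   non-overlapping.
#' @param gap_threshold Minimum silence that separates phrases, seconds.
#' @return Tibble with one row per phrase: `phrase_index`, `onset`, `offset`,
#'   `n_words`, `word_indices` (list column of row indices into `words`).
#'   Empty input gives an empty tibble.
#' @export
#' @examples
#' w <- word_tier_from_layout(c(1, 0.7, 0.8), gaps_before = c(0, 0.3, 0.6))
#' build_phrases(w)  # words 1-2 merge; word 3 starts a new phrase
build_phrases <- function(words, gap_threshold = 0.5) {
  if (gap_threshold <= 0) {
    stop_config("gap_threshold must be positive")
  }
  n <- nrow(words)
  if (n == 0L) {
    return(tibble::tibble(phrase_index = integer(0), onset = numeric(0),
                          offset = numeric(0), n_words = integer(0),
                          word_indices = list()))
  }
  if (is.unsorted(words$start) ||
      (n > 1 && any(words$start[-1] < words$end[-n] - 1e-12))) {
    stop_config("word tier must be time-ordered and non-overlapping")
  }
  gaps <- if (n > 1) words$start[-1] - words$end[-n] else numeric(0)
  # ties at the threshold split ("reached or exceeded"); guard fp noise
  new_phrase <- c(TRUE, gaps >= gap_threshold - 1e-9)
  pid <- cumsum(new_phrase)
  idx <- split(seq_len(n), pid)
  tibble::tibble(
    phrase_index = seq_along(idx),
    onset = unname(vapply(idx, function(i) words$start[i[1]], numeric(1))),
    offset = unname(vapply(idx, function(i) words$end[i[length(i)]],
                           numeric(1))),
    n_words = unname(lengths(idx)),
    word_indices = unname(idx)
  )
}

#' Count syllables in a phrase as the number of vowel phones it contains
#'
#' Every vowel-class phone counts, not only the nine long target vowels. A
#' phone is inside a phrase when its midpoint lies in `[onset, offset)`,
#' which prevents double counting at shared boundaries.
#'
#' @param phrase One row of the output of [build_phrases()] (or any list
#'   with `onset` and `offset`).
#' @param phones Phone-tier tibble with `start`, `end` and a logical vowel
#'   flag in `is_vowel` (or `is_target_vowel` as a fallback).
#' @return Integer syllable count (0 for consonant-only phrases; such
#'   phrases are excluded from articulation-rate modelling downstream).
#' @export
count_syllables <- function(phrase, phones) {
  flag <- phones[["is_vowel"]] %||% phones[["is_target_vowel"]]
  if (is.null(flag)) {
    stop_config("phone tier needs an is_vowel or is_target_vowel column")
  }
  mid <- (phones$start + phones$end) / 2
  sum(flag & mid >= phrase$onset & mid < phrase$offset)
}

#' Attach syllable counts to a phrase table
#'
#' Vectorized wrapper around [count_syllables()]; zero-syllable phrases are
#' flagged (kept for pitch analyses, excluded from rate analyses).
#'
#' @param phrases Output of [build_phrases()].
#' @param phones Phone tier as in [count_syllables()].
#' @return `phrases` with columns `n_syllables` and `rate_eligible` added.
#' @export
add_syllable_counts <- function(phrases, phones) {
  phrases$n_syllables <- vapply(seq_len(nrow(phrases)), function(i) {
    count_syllables(phrases[i, ], phones)
  }, numeric(1))
  phrases$rate_eligible <- phrases$n_syllables >= 1
  if (any(!phrases$rate_eligible)) {
    message(sum(!phrases$rate_eligible),
            " phrase(s) contain no vowel phone; excluded from rate analyses")
  }
  phrases
}
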