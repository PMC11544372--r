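# The seven acoustic measures: intonational (pitch, pitch range), temporal
# (articulation rate, vowel duration), and segmental (vowel-space areas,
# vowel variability, vowel distinctiveness).

#' Convert frequency to semitones above 10 Hz
#'
#' Pitch perception is logarithmic, so F0 values in Hz are mapped to
#' `12 * log2(f0 / 10)` semitones; 10 Hz maps to 0 and each doubling adds
#' exactly 12 semitones.
#'
#' @param f0 Frequencies in Hz (> 0).
#' @param reference Reference frequency in Hz (default 10).
#' @return Semitones above the reference.
#' @export
#' @examples
#' hz_to_semitones(c(10, 20, 440))
hz_to_semitones <- function(f0, reference = 10) {
  if (any(!is.finite(f0)) || any(f0 <= 0)) {
    stop_config("f0 must be positive and finite")
  }
  12 * log2(f0 / reference)
}

#' Inverse of [hz_to_semitones()]
#' @param st Semitones above the reference.
#' @param reference Reference frequency in Hz.
#' @return Frequencies in Hz.
#' @export
semitones_to_hz <- function(st, reference = 10) {
  reference * 2^(st / 12)
}

#' Phrase pitch and pitch range in semitones
#'
#' Phrase pitch is the phrase's mean F0 converted to semitones; pitch range
#' is the semitone difference between the phrase's highest and lowest F0.
#' Phrases with missing or non-positive F0 summaries (unvoiced phrases)
#' yield `NA` and are excluded from pitch modelling by the caller.
#'
#' @param phrases Tibble with `f0_min`, `f0_mean`, `f0_max` in Hz.
#' @return `phrases` with `pitch_st` and `pitch_range_st` columns added.
#' @export
add_pitch_measures <- function(phrases) {
  ok <- is.finite(phrases$f0_mean) & phrases$f0_mean > 0 &
    is.finite(phrases$f0_min) & phrases$f0_min > 0 &
    is.finite(phrases$f0_max) & phrases$f0_max > 0
  if (any(!ok)) {
    message(sum(!ok), " phrase(s) lack F0 summaries; excluded from pitch analyses")
  }
  phrases$pitch_st <- ifelse(ok, 12 * log2(phrases$f0_mean / 10), NA_real_)
  phrases$pitch_range_st <- ifelse(
    ok, 12 * log2(phrases$f0_max / 10) - 12 * log2(phrases$f0_min / 10),
    NA_real_)
  phrases
}

#' Articulation rate of a phrase
#'
#' Syllables per second of phonation time (phrase duration with silences
#' excluded).
#'
#' @param n_syllables Syllable count(s), >= 1.
#' @param phonation_time Phonation time(s) in seconds, > 0.
#' @return Syllables per second of phonation.
#' @export
#' @examples
#' articulation_rate(5, 1.0)
articulation_rate <- function(n_syllables, phonation_time) {
  if (any(n_syllables < 1) || any(phonation_time <= 0)) {
    stop_config("articulation rate needs n_syllables >= 1 and phonation_time > 0")
  }
  n_syllables / phonation_time
}

#' Shoelace area of a polygon in the F1-F2 plane
#'
#' Absolute value of the shoelace (surveyor's) formula over the vertices in
#' the given order. Vertices are (F1, F2) pairs in Hz, so the area is in
#' Hz^2.
#'
#' @param f1,f2 Vertex coordinates, >= 3 vertices, in traversal order.
#' @return Polygon area (>= 0).
#' @export
#' @examples
#' polygon_area(c(0, 2, 0), c(0, 0, 2))  # right triangle, area 2
polygon_area <- function(f1, f2) {
  n <- length(f1)
  if (n < 3L || length(f2) != n) {
    stop_config("polygon_area needs >= 3 (f1, f2) vertices")
  }
  j <- c(2:n, 1L)
  abs(sum(f1 * (f2[j] - f2[c(n, 1:(n - 1))]))) / 2
}

#' Vowel-space area from tokens of one speaker x register x session cell
#'
#' Computes category-mean (F1, F2) points and the shoelace area of the
#' polygon they span: the corner version uses the triangle of the three
#' corner vowels, the full version the seven border vowels in the fixed
#' phonetic traversal order. If any required category has no token the cell
#' is undefined and `NA` is returned (with a message), mirroring reduced
#' cell counts in real data.
#'
#' @param tokens Tibble with `category`, `f1`, `f2` for one cell.
#' @param which `"corner"` or `"full"`.
#' @param inventory A [vowel_inventory()].
#' @return Area in Hz^2, or `NA` if a required category is missing.
#' @export
vowel_space <- function(tokens, which = c("corner", "full"),
                        inventory = vowel_inventory()) {
  which <- match.arg(which)
  order <- if (which == "corner") inventory$corner_triple else
    inventory$border_order
  mf1 <- tapply(tokens$f1, factor(tokens$category, levels = order), mean)
  mf2 <- tapply(tokens$f2, factor(tokens$category, levels = order), mean)
  if (anyNA(mf1) || anyNA(mf2)) {
    message("vowel_space(", which, "): missing category; cell skipped")
    return(NA_real_)
  }
  polygon_area(as.numeric(mf1), as.numeric(mf2))
}

#' Within-category vowel variability
#'
#' Ellipse area `pi * sd(F1) * sd(F2)` (sample standard deviations) over the
#' tokens of one vowel category: high values mean loose, variable
#' productions; low values compact, precise ones.
#'
#' @param f1,f2 Formants (Hz) of the tokens of one category; >= 2 tokens.
#' @return Variability in Hz^2, or `NA` (with a message) for < 2 tokens.
#' @export
#' @examples
#' vowel_variability(rnorm(20, 500, 100), rnorm(20, 1500, 200))
vowel_variability <- function(f1, f2) {
  if (length(f1) < 2L || length(f2) != length(f1)) {
    message("vowel_variability: fewer than 2 tokens; cell skipped")
    return(NA_real_)
  }
  pi * stats::sd(f1) * stats::sd(f2)
}

#' Vowel distinctiveness: variance in (F1, F2) explained by category
#'
#' Between-category sum of squares over total sum of squares, computed
#' jointly over the F1 and F2 dimensions (unscaled Hz): squared distances of
#' each token's category centroid from the grand centroid, divided by
#' squared distances of the tokens themselves from the grand centroid.
#' Ranges from 0 (categories fully overlap) to 1 (every token sits on its
#' category centroid). Tokens of excluded categories (by default the close
#' front rounded vowel, which overlaps the unrounded one) are dropped first.
#'
#' @param tokens Tibble with `category`, `f1`, `f2`.
#' @param exclude Category labels dropped before computing.
#' @return Quotient in \[0, 1\], or `NA` (with a message) when fewer than two
#'   categories remain or the total sum of squares is zero.
#' @export
vowel_distinctiveness <- function(tokens, exclude = "y:") {
  tok <- tokens[!(tokens$category %in% exclude), , drop = FALSE]
  if (length(unique(tok$category)) < 2L) {
    message("vowel_distinctiveness: fewer than 2 categories; cell skipped")
    return(NA_real_)
  }
  g1 <- mean(tok$f1)
  g2 <- mean(tok$f2)
  c1 <- stats::ave(tok$f1, tok$category)
  c2 <- stats::ave(tok$f2, tok$category)
  total <- sum((tok$f1 - g1)^2 + (tok$f2 - g2)^2)
  if (total == 0) {
    message("vowel_distinctiveness: zero total sum of squares; cell skipped")
    return(NA_real_)
  }
  between <- sum((c1 - g1)^2 + (c2 - g2)^2)
  between / total
}

#' Session-level segmental summaries and per-observation measure tables
#'
#' Aggregates vowel tokens into one row per speaker x register x session
#' (corner/full vowel-space areas, mean within-category variability,
#' distinctiveness), computes per-category variability, and attaches the
#' phrase-level measures (pitch, pitch range, articulation rate) needed by
#' the modelling module.
#'
#' @param tokens Vowel-token tibble (see [generate_cohort()] for columns).
#' @param phrases Phrase tibble with F0 summaries, `n_syllables` and
#'   `phonation_time`.
#' @param inventory A [vowel_inventory()].
#' @return List of tibbles: `sessions` (one row per cell), `variability`
#'   (one row per cell x category), `phrases` (per-phrase measures).
#' @export
summarize_sessions <- function(tokens, phrases,
                               inventory = vowel_inventory()) {
  covars <- c("family_id", "speaker_id", "parent_gender", "child_gender",
              "session", "child_age_days", "register", "recording_order")
  key <- covars[covars %in% names(tokens)]
  grp <- dplyr::group_by(tokens, dplyr::across(dplyr::all_of(key)))
  sessions <- dplyr::summarise(
    grp,
    n_tokens = dplyr::n(),
    vowel_space_corner = suppressMessages(
      vowel_space(dplyr::pick(dplyr::everything()), "corner", inventory)),
    vowel_space_full = suppressMessages(
      vowel_space(dplyr::pick(dplyr::everything()), "full", inventory)),
    distinctiveness = suppressMessages(
      vowel_distinctiveness(dplyr::pick(dplyr::everything()),
                            exclude = inventory$distinctiveness_excluded)),
    .groups = "drop"
  )
  grp_cat <- dplyr::group_by(tokens,
                             dplyr::across(dplyr::all_of(c(key, "category"))))
  variability <- dplyr::summarise(
    grp_cat,
    n_tokens = dplyr::n(),
    variability = suppressMessages(vowel_variability(.data$f1, .data$f2)),
    .groups = "drop"
  )
  mean_var <- dplyr::summarise(
    dplyr::group_by(variability, dplyr::across(dplyr::all_of(key))),
    mean_variability = mean(.data$variability, na.rm = TRUE),
    .groups = "drop"
  )
  sessions <- dplyr::left_join(sessions, mean_var, by = key)
  phr <- add_pitch_measures(phrases)
  ok <- phr$n_syllables >= 1 & phr$phonation_time > 0
  phr$articulation_rate <- NA_real_
  phr$articulation_rate[ok] <- phr$n_syllables[ok] / phr$phonation_time[ok]
  list(sessions = sessions, variability = variability, phrases = phr)
}
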