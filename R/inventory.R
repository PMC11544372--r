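#' Long-vowel inventory for the formant plane
#'
#' Defines the nine long-vowel categories whose tokens are measured in the
#' F1--F2 plane, the fixed peripheral ("border") traversal order used for the
#' full vowel-space polygon, and the three corner vowels used for the
#' triangular vowel space. The close front rounded vowel (label `"y:"`)
#' belongs to the inventory but is excluded from vowel distinctiveness
#' because it overlaps the close front unrounded vowel in F1--F2.
#'
#' Category labels are ASCII transliterations of the IPA long vowels
#' (`"a:"`, `"e:"`, `"i:"`, `"u:"`, `"uu:"` for the close central rounded
#' vowel, `"y:"`, `"ae:"`, `"oe:"`, `"o:"` for the open-mid back vowel).
#'
#' @param categories Character vector of category labels.
#' @param mean_f1,mean_f2 Named numeric vectors, one entry per category:
#'   category-mean formants in Hz.
#' @param sigma_f1,sigma_f2 Named numeric vectors: within-category standard
#'   deviations in Hz.
#' @param border_order Ordered labels of the seven border vowels, the
#'   traversal order of the full vowel-space polygon.
#' @param corner_triple Ordered labels of the three corner vowels.
#' @param distinctiveness_excluded Labels dropped before computing vowel
#'   distinctiveness.
#'
#' @return An object of class `vowel_inventory` (a list with the fields
#'   above).
#' @export
#' @examples
#' inv <- vowel_inventory()
#' inv$corner_triple
vowel_inventory <- function(categories = c("i:", "e:", "ae:", "a:", "o:",
                                           "u:", "uu:", "y:", "oe:"),
                            mean_f1 = c("i:" = 280, "e:" = 400, "ae:" = 700,
                                        "a:" = 680, "o:" = 480, "u:" = 320,
                                        "uu:" = 320, "y:" = 290, "oe:" = 440),
                            mean_f2 = c("i:" = 2250, "e:" = 2000, "ae:" = 1600,
                                        "a:" = 1100, "o:" = 850, "u:" = 700,
                                        "uu:" = 1600, "y:" = 2200,
                                        "oe:" = 1500),
                            sigma_f1 = stats::setNames(rep(60, length(categories)),
                                                       categories),
                            sigma_f2 = stats::setNames(rep(100, length(categories)),
                                                       categories),
                            border_order = c("i:", "e:", "ae:", "a:", "o:",
                                             "u:", "uu:"),
                            corner_triple = c("i:", "ae:", "u:"),
                            distinctiveness_excluded = "y:") {
  if (anyDuplicated(categories)) {
    stop_config("vowel categories must be unique")
  }
  for (v in list(mean_f1, mean_f2, sigma_f1, sigma_f2)) {
    if (!all(categories %in% names(v))) {
      stop_config("formant parameter vectors must name every category")
    }
    if (any(v[categories] <= 0)) {
      stop_config("formant means and sigmas must be positive")
    }
  }
  if (!all(border_order %in% categories) ||
      !all(corner_triple %in% categories)) {
    stop_config("border_order and corner_triple must be subsets of categories")
  }
  if (length(border_order) < 3 || length(corner_triple) != 3) {
    stop_config("border_order needs >= 3 vowels; corner_triple exactly 3")
  }
  structure(
    list(
      categories = categories,
      mean_f1 = mean_f1[categories],
      mean_f2 = mean_f2[categories],
      sigma_f1 = sigma_f1[categories],
      sigma_f2 = sigma_f2[categories],
      border_order = border_order,
      corner_triple = corner_triple,
      distinctiveness_excluded = distinctiveness_excluded
    ),
    class = "vowel_inventory"
  )
}

#' Ground-truth register, age and gender effects for the cohort generator
#'
#' Collects the effect sizes injected into synthetic cohorts, on the scale
#' on which each acoustic measure is modelled. All defaults are neutral
#' (shifts 0, multiplicative factors 1): a default configuration generates
#' data with no register differences at all.
#'
#' @param pitch_shift_ids Semitones added to phrase mean pitch in
#'   infant-directed speech (IDS).
#' @param pitch_range_shift_ids Semitones added to phrase pitch range in IDS.
#' @param rate_log_ratio_ids Log syllable-rate ratio IDS vs adult-directed
#'   speech (ADS); negative values slow IDS down.
#' @param duration_log_shift_ids Shift of log vowel duration (log-ms) in IDS.
#' @param peripheralization_ids Multiplicative expansion of IDS category
#'   means away from the vowel-space centroid (1 = none).
#' @param variability_inflation_ids Multiplicative factor on the
#'   within-category formant standard deviations in IDS (1 = none).
#' @param age_slopes Named numeric vector of per-measure, per-register linear
#'   slopes on z-scored child age. Names have the form
#'   `"<measure>_<register>"` with measure in `pitch`, `pitch_range`,
#'   `log_rate`, `log_duration` and register in `ads`, `ids`
#'   (e.g. `c(pitch_ads = -0.5)`). Unnamed measures get slope 0.
#' @param gender_offsets Named numeric vector of additive offsets applied to
#'   mothers' values relative to fathers', per measure (same measure names).
#' @param father_formant_scale Multiplicative factor applied to fathers'
#'   formant means and sigmas, reflecting the longer male vocal tract.
#' @param seed Integer; fixes every random draw of the generator. Two runs
#'   with identical plan, inventory and effects are identical.
#'
#' @return An object of class `effect_config`.
#' @export
#' @examples
#' eff <- effect_config(pitch_shift_ids = 2.5, seed = 42)
effect_config <- function(pitch_shift_ids = 0,
                          pitch_range_shift_ids = 0,
                          rate_log_ratio_ids = 0,
                          duration_log_shift_ids = 0,
                          peripheralization_ids = 1,
                          variability_inflation_ids = 1,
                          age_slopes = numeric(0),
                          gender_offsets = numeric(0),
                          father_formant_scale = 0.85,
                          seed = 1L) {
  if (peripheralization_ids <= 0 || variability_inflation_ids <= 0 ||
      father_formant_scale <= 0) {
    stop_config("multiplicative effect factors must be > 0")
  }
  if (length(age_slopes) && is.null(names(age_slopes))) {
    stop_config("age_slopes must be a named numeric vector")
  }
  if (length(gender_offsets) && is.null(names(gender_offsets))) {
    stop_config("gender_offsets must be a named numeric vector")
  }
  structure(
    list(
      pitch_shift_ids = pitch_shift_ids,
      pitch_range_shift_ids = pitch_range_shift_ids,
      rate_log_ratio_ids = rate_log_ratio_ids,
      duration_log_shift_ids = duration_log_shift_ids,
      peripheralization_ids = peripheralization_ids,
      variability_inflation_ids = variability_inflation_ids,
      age_slopes = age_slopes,
      gender_offsets = gender_offsets,
      father_formant_scale = father_formant_scale,
      seed = as.integer(seed)
    ),
    class = "effect_config"
  )
}

#' Longitudinal cohort layout
#'
#' Describes the design of a synthetic cohort: families followed over five
#' sessions at roughly three-month intervals, each surviving family recorded
#' in both registers (ADS and IDS) at every session, with one parent (mother
#' or father) per session chosen by a session-specific probability. Defaults
#' mirror a 69-family cohort recorded at child ages of about 6, 9, 12, 15
#' and 18 months, with mothers predominant at the first and the last two
#' sessions and fathers predominant at sessions two and three (the typical
#' Norwegian parental-leave pattern), and mild monotone attrition.
#'
#' @param n_families Number of families at study onset.
#' @param session_labels Labels of the longitudinal sessions.
#' @param session_ages Target child age in days at each session; strictly
#'   increasing.
#' @param session_age_sd Standard deviation (days) of scheduling jitter
#'   around the target ages.
#' @param attrition_per_session Probability that a family drops out before
#'   each follow-up session (dropout is permanent).
#' @param parent_schedule Per-session probability that the recorded parent is
#'   the mother; recycled to the number of sessions.
#' @param prop_girls Probability a child is a girl.
#' @param tokens_per_category_per_session Vowel tokens generated per vowel
#'   category in each recording.
#' @param phrases_per_recording Phrases generated per recording.
#'
#' @return An object of class `cohort_plan`.
#' @export
#' @examples
#' plan <- cohort_plan(n_families = 4, phrases_per_recording = 6,
#'                     tokens_per_category_per_session = 2)
cohort_plan <- function(n_families = 69,
                        session_labels = paste0("T", 1:5),
                        session_ages = c(182, 276, 365, 452, 542),
                        session_age_sd = 8,
                        attrition_per_session = 0.033,
                        parent_schedule = c(0.985, 0.394, 0.355, 0.721, 0.717),
                        prop_girls = 0.62,
                        tokens_per_category_per_session = 10,
                        phrases_per_recording = 36) {
  if (!is_count(n_families)) {
    stop_config("n_families must be a positive integer")
  }
  if (length(session_labels) != length(session_ages)) {
    stop_config("session_labels and session_ages must have equal length")
  }
  if (any(diff(session_ages) <= 0)) {
    stop_config("session_ages must be strictly increasing")
  }
  if (!is_prob(attrition_per_session) || !is_prob(parent_schedule) ||
      !is_prob(prop_girls)) {
    stop_config("probabilities must lie in [0, 1]")
  }
  if (!is_count(tokens_per_category_per_session) ||
      !is_count(phrases_per_recording)) {
    stop_config("per-session counts must be positive integers")
  }
  structure(
    list(
      n_families = as.integer(n_families),
      session_labels = session_labels,
      session_ages = session_ages,
      session_age_sd = session_age_sd,
      attrition_per_session = attrition_per_session,
      parent_schedule = rep_len(parent_schedule, length(session_labels)),
      prop_girls = prop_girls,
      tokens_per_category_per_session =
        as.integer(tokens_per_category_per_session),
      phrases_per_recording = as.integer(phrases_per_recording)
    ),
    class = "cohort_plan"
  )
}
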