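#' Generate a synthetic longitudinal IDS/ADS cohort
#'
#' Simulates a longitudinal register-comparison study: `n_families` families
#' followed over repeated sessions, each surviving family contributing one
#' adult-directed (ADS) and one infant-directed (IDS) recording per session,
#' recorded from one parent (mother or father) chosen per session. Every
#' injected effect (register shifts, age slopes, gender offsets) is known, so
#' downstream estimates can be compared against ground truth.
#'
#' Phrase-level data carry min/mean/max F0 summaries (Hz), syllable counts
#' and phonation times; vowel tokens carry F1/F2 (Hz) drawn from per-category
#' bivariate Gaussians with diagonal covariance, and durations (ms) drawn
#' log-normally. Syllable counts are Poisson given phonation time, so the
#' articulation-rate model's generating process matches its likelihood.
#'
#' The age covariate on which ground-truth slopes act is z-scored child age,
#' centred and scaled by the plan's target session ages; the constants used
#' are returned in `truth`.
#'
#' @param plan A [cohort_plan()].
#' @param inventory A [vowel_inventory()].
#' @param effects An [effect_config()]; `effects$seed` fixes all draws.
#'
#' @return A list of class `regspeech_cohort` with elements
#'   \describe{
#'     \item{tokens}{tibble, one row per vowel token: `family_id`,
#'       `speaker_id`, `parent_gender`, `child_gender`, `session`,
#'       `child_age_days`, `register`, `recording_order`, `category`, `word`,
#'       `f1`, `f2`, `duration_ms`.}
#'     \item{phrases}{tibble, one row per phrase: the same covariates plus
#'       `recording_id`, `phrase_id`, `onset`, `offset`, `n_syllables`,
#'       `phonation_time`, `f0_min`, `f0_mean`, `f0_max`.}
#'     \item{roster}{tibble, one row per family x session actually recorded.}
#'     \item{truth}{list of the injected effects and generator constants.}
#'   }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_plan(n_families = 3,
#'                                    phrases_per_recording = 5,
#'                                    tokens_per_category_per_session = 2),
#'                        vowel_inventory(),
#'                        effect_config(pitch_shift_ids = 2.5, seed = 7))
#' nrow(coh$roster)
generate_cohort <- function(plan = cohort_plan(),
                            inventory = vowel_inventory(),
                            effects = effect_config()) {
  stopifnot(inherits(plan, "cohort_plan"),
            inherits(inventory, "vowel_inventory"),
            inherits(effects, "effect_config"))
  with_seed(effects$seed, generate_cohort_impl(plan, inventory, effects))
}

# Generator constants: population baselines on each measure's model scale.
cohort_baselines <- function() {
  list(
    pitch_mother = 52.5, pitch_father = 43.5, pitch_parent_sd = 1.5,
    pitch_phrase_sd = 2.5,
    range_base = 12, range_parent_sd = 1.2, range_phrase_sd = 3,
    range_floor = 0.3,
    log_rate_base = log(5.0), log_rate_parent_sd = 0.05,
    log_duration_base = log(120), log_duration_parent_sd = 0.08,
    log_duration_token_sd = 0.25,
    formant_parent_scale_sd = 0.04,
    phonation_meanlog = log(1.2), phonation_sdlog = 0.4,
    phrase_pause = 0.7, phrase_stretch = 1.15
  )
}

generate_cohort_impl <- function(plan, inventory, effects) {
  b <- cohort_baselines()
  n_sessions <- length(plan$session_labels)
  age_center <- mean(plan$session_ages)
  age_scale <- stats::sd(plan$session_ages)

  # Family-level design: child gender, recording order, dropout session.
  child_gender <- ifelse(stats::runif(plan$n_families) < plan$prop_girls,
                         "girl", "boy")
  recording_order <- rep_len(c("ads_first", "ids_first"), plan$n_families)
  # Monotone dropout: first session (2..n) before which the family leaves.
  drop_draw <- matrix(stats::runif(plan$n_families * (n_sessions - 1)) <
                        plan$attrition_per_session,
                      nrow = plan$n_families)
  last_session <- apply(drop_draw, 1, function(d) {
    w <- which(d)
    if (length(w)) w[1] else n_sessions
  })

  # Parent-level baselines (two potential parents per family).
  parent_key <- function(fam, gender) paste0("F", fam, "_", gender)
  parents <- expand.grid(family = seq_len(plan$n_families),
                         gender = c("mother", "father"),
                         stringsAsFactors = FALSE)
  parents$id <- parent_key(parents$family, parents$gender)
  parents$pitch_base <- ifelse(parents$gender == "mother",
                               b$pitch_mother, b$pitch_father) +
    stats::rnorm(nrow(parents), 0, b$pitch_parent_sd)
  parents$range_base <- b$range_base +
    stats::rnorm(nrow(parents), 0, b$range_parent_sd)
  parents$log_rate_base <- b$log_rate_base +
    stats::rnorm(nrow(parents), 0, b$log_rate_parent_sd)
  parents$log_duration_base <- b$log_duration_base +
    stats::rnorm(nrow(parents), 0, b$log_duration_parent_sd)
  parents$formant_scale <- ifelse(parents$gender == "mother", 1,
                                  effects$father_formant_scale) *
    exp(stats::rnorm(nrow(parents), 0, b$formant_parent_scale_sd))
  rownames(parents) <- parents$id

  # Session roster (vectorized over family x session).
  fam_idx <- rep(seq_len(plan$n_families), last_session)
  s_idx <- unlist(lapply(last_session, seq_len))
  n_ros <- length(fam_idx)
  age <- round(plan$session_ages[s_idx] +
                 stats::rnorm(n_ros, 0, plan$session_age_sd))
  pg <- ifelse(stats::runif(n_ros) < plan$parent_schedule[s_idx],
               "mother", "father")
  roster <- tibble::tibble(
    family_id = paste0("F", fam_idx),
    session = plan$session_labels[s_idx],
    session_index = s_idx,
    child_age_days = age,
    parent_gender = pg,
    speaker_id = parent_key(fam_idx, pg),
    child_gender = child_gender[fam_idx],
    recording_order = recording_order[fam_idx]
  )

  # One row per recording: roster x {ADS, IDS}.
  rec <- roster[rep(seq_len(n_ros), each = 2L), ]
  rec$register <- rep(c("ADS", "IDS"), n_ros)
  rec$recording_id <- paste(rec$family_id, rec$session, rec$register,
                            sep = "_")
  ids <- rec$register == "IDS"
  par <- parents[rec$speaker_id, ]
  age_z <- (rec$child_age_days - age_center) / age_scale
  mother <- rec$parent_gender == "mother"

  eff_slope <- function(measure) {
    ifelse(ids, lookup_effect(effects$age_slopes, paste0(measure, "_ids")),
           lookup_effect(effects$age_slopes, paste0(measure, "_ads"))) * age_z
  }
  eff_gender <- function(measure) {
    mother * lookup_effect(effects$gender_offsets, measure)
  }

  ## --- phrase level ---
  np <- plan$phrases_per_recording
  n_rec <- nrow(rec)
  ri <- rep(seq_len(n_rec), each = np)      # recording index per phrase row
  n_phr <- n_rec * np
  pitch_mu <- par$pitch_base + ids * effects$pitch_shift_ids +
    eff_slope("pitch") + eff_gender("pitch")
  range_mu <- par$range_base + ids * effects$pitch_range_shift_ids +
    eff_slope("pitch_range") + eff_gender("pitch_range")
  log_rate <- par$log_rate_base + ids * effects$rate_log_ratio_ids +
    eff_slope("log_rate") + eff_gender("log_rate")
  pitch_st <- pitch_mu[ri] + stats::rnorm(n_phr, 0, b$pitch_phrase_sd)
  range_st <- pmax(b$range_floor,
                   range_mu[ri] + stats::rnorm(n_phr, 0, b$range_phrase_sd))
  u <- stats::runif(n_phr, 0.3, 0.7)
  phonation <- stats::rlnorm(n_phr, b$phonation_meanlog, b$phonation_sdlog)
  n_syll <- stats::rpois(n_phr, exp(log_rate[ri]) * phonation)
  dur <- phonation * b$phrase_stretch
  # sequential within-recording layout separated by a fixed pause
  step_end <- stats::ave(dur + b$phrase_pause, ri, FUN = cumsum)
  onset <- step_end - dur
  phrases <- tibble::tibble(
    family_id = rec$family_id[ri], speaker_id = rec$speaker_id[ri],
    parent_gender = rec$parent_gender[ri], child_gender = rec$child_gender[ri],
    session = rec$session[ri], child_age_days = rec$child_age_days[ri],
    register = rec$register[ri], recording_order = rec$recording_order[ri],
    recording_id = rec$recording_id[ri],
    phrase_id = paste0(rec$recording_id[ri], "_p",
                       rep(seq_len(np), n_rec)),
    onset = onset, offset = onset + dur,
    n_syllables = n_syll, phonation_time = phonation,
    f0_min = semitones_to_hz(pitch_st - range_st * u),
    f0_mean = semitones_to_hz(pitch_st),
    f0_max = semitones_to_hz(pitch_st - range_st * u + range_st)
  )

  ## --- token level ---
  # population category means for the 4 gender x register combinations
  mean_tab <- list()
  for (g in c("mother", "father")) {
    for (reg in c("ADS", "IDS")) {
      mean_tab[[paste(g, reg)]] <-
        expected_category_means(inventory, effects, gender = g,
                                register = reg)
    }
  }
  nt <- plan$tokens_per_category_per_session
  n_cat <- length(inventory$categories)
  ti <- rep(seq_len(n_rec), each = n_cat * nt)   # recording index per token
  cat_i <- rep(rep(seq_len(n_cat), each = nt), n_rec)
  n_tok <- length(ti)
  combo <- paste(rec$parent_gender, rec$register)[ti]
  mt <- dplyr::bind_rows(lapply(names(mean_tab), function(k) {
    tibble::tibble(combo = k, mean_tab[[k]])
  }))
  mi <- match(paste(combo, inventory$categories[cat_i]),
              paste(mt$combo, mt$category))
  mu_f1 <- mt$f1[mi]
  mu_f2 <- mt$f2[mi]
  # per-parent vocal-tract scale jitter on top of the population means
  scale_extra <- (par$formant_scale /
                    ifelse(mother, 1, effects$father_formant_scale))[ti]
  sig_scale <- (ifelse(mother, 1, effects$father_formant_scale) *
                  ifelse(ids, effects$variability_inflation_ids, 1))[ti]
  category <- inventory$categories[cat_i]
  log_dur_mu <- par$log_duration_base +
    ids * effects$duration_log_shift_ids +
    eff_slope("log_duration") + eff_gender("log_duration")
  tokens <- tibble::tibble(
    family_id = rec$family_id[ti], speaker_id = rec$speaker_id[ti],
    parent_gender = rec$parent_gender[ti], child_gender = rec$child_gender[ti],
    session = rec$session[ti], child_age_days = rec$child_age_days[ti],
    register = rec$register[ti], recording_order = rec$recording_order[ti],
    recording_id = rec$recording_id[ti],
    category = category,
    word = paste0("w_", sub(":", "", category, fixed = TRUE), "_",
                  sample.int(5, n_tok, replace = TRUE)),
    f1 = stats::rnorm(n_tok, mu_f1 * scale_extra,
                      inventory$sigma_f1[category] * sig_scale),
    f2 = stats::rnorm(n_tok, mu_f2 * scale_extra,
                      inventory$sigma_f2[category] * sig_scale),
    duration_ms = exp(log_dur_mu[ti] +
                        stats::rnorm(n_tok, 0, b$log_duration_token_sd))
  )

  structure(
    list(
      tokens = tokens,
      phrases = phrases,
      roster = roster,
      truth = list(
        effects = effects,
        baselines = b,
        age_center = age_center,
        age_scale = age_scale,
        parents = tibble::as_tibble(parents)
      )
    ),
    class = "regspeech_cohort"
  )
}

#' Ground-truth category means under a given register and parent gender
#'
#' Returns the population F1/F2 category means after applying the father
#' vocal-tract scaling and (for IDS) the peripheralization expansion away
#' from the vowel-space centroid. Used both by the generator and by tests
#' comparing estimated vowel-space areas against truth.
#'
#' @inheritParams generate_cohort
#' @param gender `"mother"` or `"father"`.
#' @param register `"ADS"` or `"IDS"`.
#' @return A tibble with columns `category`, `f1`, `f2`.
#' @export
expected_category_means <- function(inventory, effects,
                                    gender = "mother", register = "ADS") {
  scale <- if (gender == "father") effects$father_formant_scale else 1
  f1 <- inventory$mean_f1 * scale
  f2 <- inventory$mean_f2 * scale
  if (register == "IDS" && effects$peripheralization_ids != 1) {
    c1 <- mean(f1)
    c2 <- mean(f2)
    f1 <- c1 + effects$peripheralization_ids * (f1 - c1)
    f2 <- c2 + effects$peripheralization_ids * (f2 - c2)
  }
  tibble::tibble(category = inventory$categories,
                 f1 = unname(f1), f2 = unname(f2))
}
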