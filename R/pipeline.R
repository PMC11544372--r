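# End-to-end pipeline: synthetic cohort -> TextGrid/WAV fixtures ->
# segmentation -> phonation -> acoustic measures -> model tables/fits.

# Audio layout for one recording: voiced span of each phrase's phonation
# time at the phrase onset, silence elsewhere.
recording_layout <- function(phrases) {
  phrases <- phrases[order(phrases$onset), , drop = FALSE]
  spans <- list()
  cursor <- 0
  for (i in seq_len(nrow(phrases))) {
    p <- phrases[i, ]
    if (p$onset > cursor) {
      spans[[length(spans) + 1L]] <- c(p$onset - cursor, 0)
    }
    voiced <- min(p$phonation_time, p$offset - p$onset)
    spans[[length(spans) + 1L]] <- c(voiced, 1)
    if (p$offset > p$onset + voiced) {
      spans[[length(spans) + 1L]] <- c(p$offset - p$onset - voiced, 0)
    }
    cursor <- p$offset
  }
  m <- do.call(rbind, spans)
  data.frame(duration = m[, 1], voiced = m[, 2] == 1)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort, materializes a subset of recordings as TextGrid and
#' WAV files, re-reads them, rebuilds phrases with the 500 ms pause rule,
#' recounts syllables from the phone tier, re-detects phonation time from
#' the audio, computes all acoustic measures, and (optionally) fits the
#' requested model families with the full-null comparison and interaction
#' pruning. Recordings not materialized as audio keep the generator's
#' phonation times, so cohort-scale model fits stay fast while the audio
#' path is still exercised end to end.
#'
#' @param plan A [cohort_plan()].
#' @param inventory A [vowel_inventory()].
#' @param effects An [effect_config()].
#' @param dir Output directory for TextGrid/WAV/CSV/ground-truth files;
#'   `NULL` for in-memory only (no audio path).
#' @param n_audio_recordings Number of recordings written as TextGrid + WAV
#'   and re-analysed from file.
#' @param audio_rate Sample rate for synthesized audio. The default 16 kHz
#'   keeps fixture files small; the detector's frame parameters are
#'   rate-independent in dB terms.
#' @param fit_families Integer vector of model families (1-8) to fit, or
#'   `NULL` to skip fitting.
#' @param alpha Interaction-retention threshold for pruning.
#' @param prune Whether to prune interactions after a significant full-null
#'   comparison.
#' @return List with `cohort`, `measures` (output of
#'   [summarize_sessions()]), `segmentation_check` (per-recording phrase and
#'   syllable conservation for the materialized recordings), `models` (one
#'   entry per fitted family: `full`, `null`, `comparison`, `reduced`,
#'   `trace`), and `files`.
#' @export
run_pipeline <- function(plan = cohort_plan(), inventory = vowel_inventory(),
                         effects = effect_config(), dir = NULL,
                         n_audio_recordings = 2, audio_rate = 16000,
                         fit_families = NULL, alpha = 0.1, prune = TRUE) {
  cohort <- generate_cohort(plan, inventory, effects)
  phrases <- cohort$phrases
  files <- character(0)
  seg_check <- NULL

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rec_ids <- utils::head(unique(phrases$recording_id), n_audio_recordings)
    checks <- list()
    for (rid in rec_ids) {
      ph <- phrases[phrases$recording_id == rid, , drop = FALSE]
      ali <- generate_alignment(ph, vowel_categories = inventory$categories,
                                seed = effects$seed)
      tg_path <- file.path(dir, paste0(rid, ".TextGrid"))
      write_textgrid(list(words = ali$words, phones = ali$phones), tg_path)
      wav_path <- file.path(dir, paste0(rid, ".wav"))
      write_wav(generate_waveform(recording_layout(ph), rate = audio_rate,
                                  seed = effects$seed), wav_path)
      files <- c(files, tg_path, wav_path)

      tiers <- read_textgrid(tg_path, vowel_categories = inventory$categories)
      seg <- build_phrases(tiers$words)
      seg <- add_syllable_counts(seg, tiers$phones)
      wav <- read_wav(wav_path)
      # keep the detector's frame/hop duration (~46 ms / ~12 ms) constant
      # across sample rates
      cfg <- phonation_config(
        frame_length = max(64L, round(2048 * audio_rate / 44100)),
        hop_length = max(16L, round(512 * audio_rate / 44100)))
      seg <- add_phonation_times(wav, seg, cfg)
      ph <- ph[order(ph$onset), , drop = FALSE]
      checks[[rid]] <- tibble::tibble(
        recording_id = rid,
        n_phrases_truth = nrow(ph),
        n_phrases_detected = nrow(seg),
        n_syllables_truth = sum(ph$n_syllables),
        n_syllables_detected = sum(seg$n_syllables),
        phonation_truth = sum(ph$phonation_time),
        phonation_detected = sum(seg$phonation_time)
      )
      if (nrow(seg) == nrow(ph)) {
        # replace generator phonation with the value detected from audio
        idx <- which(phrases$recording_id == rid)[order(
          phrases$onset[phrases$recording_id == rid])]
        phrases$phonation_time[idx] <- seg$phonation_time
        phrases$n_syllables[idx] <- seg$n_syllables
      }
    }
    seg_check <- dplyr::bind_rows(checks)
  }

  measures <- summarize_sessions(cohort$tokens, phrases, inventory)

  models <- list()
  for (fid in fit_families %||% integer(0)) {
    spec <- model_spec(fid)
    d <- prepare_covariates(
      switch(spec$level,
             phrases = measures$phrases,
             tokens = cohort$tokens,
             sessions = measures$sessions,
             variability = measures$variability),
      spec)
    full <- fit_model(d, spec)
    null <- fit_model(d, spec, null_model_terms(spec))
    cmp <- full_null_comparison(full, null)
    reduced <- NULL
    tr <- NULL
    if (prune && cmp$p_value <= 0.05) {
      pr <- prune_interactions(d, spec, alpha = alpha)
      reduced <- pr$fit
      tr <- pr$trace
    }
    models[[paste0("family_", fid)]] <- list(
      spec = spec, data = d, full = full, null = null, comparison = cmp,
      reduced = reduced, trace = tr)
  }

  if (!is.null(dir)) {
    tf <- write_tables(cohort$tokens, measures$phrases, measures$sessions, dir)
    gt <- file.path(dir, "ground_truth.json")
    write_ground_truth(cohort, gt)
    files <- c(files, unname(tf), gt)
  }

  list(cohort = cohort, measures = measures, segmentation_check = seg_check,
       models = models, files = files)
}
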