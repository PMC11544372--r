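# Tidy CSV export/import of cohort tables.
#
# Column dictionary (all CSVs are RFC 4180, UTF-8, "." decimal separator):
#   tokens.csv   one row per vowel token: family_id, speaker_id,
#                parent_gender, child_gender, session, child_age_days,
#                register, recording_order, recording_id, category, word,
#                f1 (Hz), f2 (Hz), duration_ms (ms)
#   phrases.csv  one row per phrase: the same covariates plus phrase_id,
#                onset (s), offset (s), n_syllables, phonation_time (s),
#                f0_min/f0_mean/f0_max (Hz)
#   sessions.csv one row per speaker x register x session summary (see
#                summarize_sessions())
# Times are seconds everywhere except vowel duration, which is exported in
# milliseconds (the unit in which durations are modelled).

#' Write cohort tables to CSV
#'
#' @param tokens Vowel-token tibble (may have zero rows; a header-only CSV
#'   is written).
#' @param phrases Phrase tibble.
#' @param summaries Optional session-summary tibble.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_tables <- function(tokens, phrases, summaries = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(tokens = file.path(dir, "tokens.csv"),
             phrases = file.path(dir, "phrases.csv"))
  utils::write.csv(tokens, files[["tokens"]], row.names = FALSE)
  utils::write.csv(phrases, files[["phrases"]], row.names = FALSE)
  if (!is.null(summaries)) {
    files <- c(files, sessions = file.path(dir, "sessions.csv"))
    utils::write.csv(summaries, files[["sessions"]], row.names = FALSE)
  }
  invisible(files)
}

#' Read a cohort CSV table
#'
#' @param path CSV file written by [write_tables()] (or following its column
#'   dictionary).
#' @return A tibble.
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write the ground-truth sidecar of a synthetic cohort
#'
#' Serializes the injected effects and generator constants to JSON next to
#' the cohort tables, so that downstream estimates can always be compared
#' with the truth that generated them.
#'
#' @param cohort A `regspeech_cohort` from [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  truth <- cohort$truth
  payload <- list(
    effects = unclass(truth$effects),
    age_center = truth$age_center,
    age_scale = truth$age_scale,
    baselines = truth$baselines
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
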