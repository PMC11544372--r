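Package: regspeech
Title: Acoustic Analysis of Infant-Directed versus Adult-Directed Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for register comparisons in speech
    recordings: phrase segmentation from word-level forced-alignment tiers
    (500 ms pause rule), energy-based phonation-time detection from audio,
    seven acoustic measures (pitch and pitch range in semitones,
    articulation rate, vowel duration, corner and full vowel-space areas,
    within-category vowel variability, vowel distinctiveness), and a
    mixed-model inference protocol (full-null likelihood-ratio comparison
    with iterative interaction pruning) for register-by-age-by-parent-gender
    designs. Includes a synthetic longitudinal cohort generator with known
    ground-truth effects so that every stage is testable without access to
    raw recordings, plus readers and writers for Praat TextGrid, mono PCM
    WAV and tidy CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    lme4,
    glmmTMB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
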