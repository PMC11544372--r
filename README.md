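# regspeech

Acoustic comparison of infant-directed speech (IDS) and adult-directed
speech (ADS) in longitudinal register-study designs.

When a parent reads the same book to their infant and to an adult, the two
renditions differ systematically: IDS is higher in pitch, wider in pitch
range, slower, and produced with longer, more peripheral and more variable
vowels. Studies of how this contrast develops record both registers from
the same parent at repeated sessions across infancy and model each
acoustic measure as a function of register, child age, parent gender and
their interactions. `regspeech` implements that pipeline end to end for
researchers in developmental psycholinguistics and bioacoustics:

* **I/O** — Praat TextGrid reading/writing (long and short text formats,
  UTF-8/UTF-16), mono PCM WAV (16/24-bit), tidy CSV tables.
* **Segmentation** — phrases as maximal word runs with no internal pause
  ≥ 500 ms (`build_phrases()`), syllables as vowel-phone counts.
* **Phonation time** — two-step energy detector: candidate segments within
  20 dB of the peak frame energy, kept as voiced when their RMS exceeds
  `quantile(|x|, 0.99) × 10^(−25/20)` (`phonation_time()`).
* **Seven measures** — pitch and pitch range in semitones above 10 Hz
  (`12 log₂(F0/10)`); articulation rate (syllables per second phonation);
  vowel duration (ms); corner (/i:/-/æ:/-/u:/) and full seven-vowel
  shoelace vowel-space areas (Hz²); within-category variability
  `π σF1 σF2`; distinctiveness as between-category over total sum of
  squares in the F1–F2 plane.
* **Inference** — eight mixed-model families (lme4, glmmTMB) sharing one
  register × age × parent-gender fixed-effects skeleton, tested by a
  full–null likelihood-ratio comparison and reduced by iterative pruning
  of non-significant interactions (`fit_model()`,
  `full_null_comparison()`, `prune_interactions()`).
* **Synthetic cohorts** — a seeded generator of longitudinal IDS/ADS
  cohorts with known injected effects (`generate_cohort()`), plus TextGrid
  and audio fixture generators, so the whole pipeline is testable without
  any real recordings.

## Worked example

Generate a 40-family cohort with a +2.5 semitone IDS pitch shift, compute
the measures, and test the register effect with the full–null comparison:

```r
library(regspeech)

coh <- generate_cohort(
  cohort_plan(n_families = 40, phrases_per_recording = 8,
              tokens_per_category_per_session = 4),
  vowel_inventory(),
  effect_config(pitch_shift_ids = 2.5, seed = 1))

m    <- summarize_sessions(coh$tokens, coh$phrases)
spec <- model_spec(1)                      # family 1: phrase pitch
d    <- prepare_covariates(m$phrases, spec)
full <- fit_model(d, spec)
null <- fit_model(d, spec, null_model_terms(spec))
full_null_comparison(full, null)
```

This prints (seed 1):

```
full-null LRT: chi^2 = 119.6, df = 5, p = 3.81e-24

  term                estimate    se
1 (Intercept)            43.7  0.457
2 parent_gendermother     8.74 0.587
3 registerIDS             2.18 0.150
```

The comparison rejects decisively: register (with its interactions, 5
terms) matters for pitch. The `registerIDS` coefficient estimates the
IDS−ADS shift for the reference cells (fathers, mean age) at 2.18 st —
the injected truth of 2.5 st is inside its sampling range, and averaging
over seeds recovers it without bias (see the acceptance script). The
intercept is the ADS baseline for fathers (≈ 43.7 st ≈ 119 Hz) and mothers
sit about 8.7 st higher.

A one-command end-to-end run (cohort → TextGrid/WAV → segmentation →
phonation → measures → models) is available from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/regspeech.R", package="regspeech"))') \
    pipeline --out-dir results/ --seed 1 --pitch-shift 2.5 --families 1
```

with further subcommands `segment`, `phonation`, `measures` and `model`
for the individual stages.

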