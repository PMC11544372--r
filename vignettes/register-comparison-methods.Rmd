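---
title: "Measuring and modelling infant-directed speech: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling infant-directed speech: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regspeech)
```

## The problem

When parents talk to their infants they shift register: infant-directed
speech (IDS) tends to be higher-pitched, wider in pitch range, slower, and
produced with longer and acoustically more exaggerated vowels than the
adult-directed speech (ADS) of the same speaker. Longitudinal studies of
this phenomenon record each parent reading the same material to their
infant and to an adult at repeated sessions across the first years of life,
and ask how the IDS--ADS contrast changes with the child's age and between
mothers and fathers.

`regspeech` implements the measurement and inference pipeline for such a
design: phrase segmentation from forced-alignment word tiers, energy-based
phonation-time detection from audio, seven acoustic measures, and a
mixed-model protocol comparing registers across age and parent gender.
Because the raw recordings of any particular study are large and not
redistributable, the package ships a synthetic cohort generator with known
ground truth; every stage of the pipeline is validated against that truth.

## Phrase segmentation

A *phrase* is a maximal run of words in which no inter-word pause reaches
500 ms; a pause of 500 ms or more starts a new phrase (`build_phrases()`,
`gap_threshold = 0.5` s). The tie at exactly the threshold splits. Because
timestamps carry floating-point noise from upstream arithmetic, the
comparison uses a 1 ns guard (`gap >= threshold - 1e-9`); one nanosecond is
six orders of magnitude below the 10 ms resolution of forced alignment, so
the guard cannot change any decision about real data.

Syllables are counted as vowel phones (`count_syllables()`): every
vowel-class phone counts, not only the nine long target vowels used for the
segmental measures. A phone belongs to a phrase when its midpoint lies in
`[onset, offset)`, which prevents double counting when a phone abuts a
phrase boundary. Phrases without any vowel phone are kept for the pitch
measures but flagged and excluded from articulation-rate modelling.

## Phonation time

The detector (`phonation_time()`) follows a two-step energy logic:

1. **Candidate segmentation.** Per-frame RMS energy (frame 2048 samples,
   hop 512 at 44.1 kHz, i.e. about 46 ms / 12 ms; both configurable) is
   compared with the peak frame energy; maximal runs of frames within
   `split_top_db` (default 20 dB) of the peak form candidate segments.
2. **Voicing decision.** A candidate is voiced when its mean frame RMS
   exceeds an amplitude threshold.

The threshold combines a decibel floor with a robust amplitude peak:
`quantile(|x|, 0.99) * 10^(-25/20)`, i.e. 25 dB below the 0.99 amplitude
quantile. The published description of this rule names its two ingredients
(the −25 dB level and the 0.99 quantile) without stating how they combine;
multiplying the quantile by the dB factor is the combination that keeps the
detector fully scale-invariant, and it is isolated in `voiced_threshold()`
so an alternative rule can be swapped in via configuration. Phonation time
is the summed duration of voiced candidates, which cannot exceed the input
duration and is invariant under amplitude rescaling (both steps scale with
the waveform).

Two further choices the published description leaves open: energy is
computed per frame (not per sample), and detection runs on per-phrase
slices of the recording rather than the whole file, so silence at a
phrase's edges reduces its phonation time but never its syllable count.
Frame quantization makes boundaries accurate only to about one hop, which
is why recovery is asserted at ±10% + 50 ms, not exactly.

## Acoustic measures

* **Pitch** — phrase mean F0 converted to semitones above 10 Hz,
  `12 log2(F0/10)`. The conversion is applied to the phrase's mean-Hz
  summary (the alternative — averaging per-sample semitones — is not
  available from min/mean/max summaries).
* **Pitch range** — semitone difference between the phrase's F0 maximum
  and minimum; non-negative by construction.
* **Articulation rate** — syllables per second of phonation time. In the
  Poisson model the raw syllable count is the response and log phonation
  time an offset, so the rate is modelled rather than precomputed.
* **Vowel duration** — token duration in ms; modelled as log duration
  after rounding to the nearest 10 ms (absorbing sub-step differences
  between manually and automatically placed boundaries).
* **Vowel-space area** — shoelace polygon area (Hz²) over category-mean
  (F1, F2) points: a corner triangle over the three peripheral vowels and
  a full seven-vowel border polygon in a fixed phonetic traversal order.
  With empirical means the border polygon can in principle self-intersect;
  the absolute shoelace value is returned and the cell flagged. Areas are
  computed in Hz²; divide by 10⁶ for kHz² display.
* **Vowel variability** — per-category ellipse area `π · sd(F1) · sd(F2)`
  with sample (n−1) standard deviations (the population/sample choice is
  not specified in the source description; sample SD is the conservative
  default).
* **Vowel distinctiveness** — between-category over total sum of squares
  of (F1, F2) jointly, in unscaled Hz, equal to the variance explained by
  a one-way classification and bounded in [0, 1]. The close front rounded
  vowel is excluded because it overlaps the unrounded one in the F1–F2
  plane.

Cells require at least one token per polygon category (areas) and at least
two tokens (variability); failing cells are skipped with a log message,
mirroring the reduced cell counts such measures have in real data.

## The model families

Eight families share a fixed-effects skeleton — register, z-scored child
age, parent gender, their interactions up to order three, plus child
gender, recording order, the parent-by-child gender interaction, and (for
phrase-level responses) z-scored phrase onset with its two-way interactions
with the target terms:

| family | response | error family |
|---|---|---|
| 1 | pitch (st) | Gaussian |
| 2 | pitch range (st) | Gaussian |
| 3 | syllable count, log phonation offset | Poisson |
| 4 | log vowel duration (10 ms rounding) | Gaussian |
| 5/6 | corner / full vowel-space area (Hz²) | Gaussian |
| 7 | log vowel variability | Gaussian |
| 8 | vowel distinctiveness | beta, logit link |

Inference follows a **full–null comparison**: the null model drops register
and every interaction containing register and the likelihood-ratio test of
full against null gives one overall p-value for the register complex,
avoiding cryptic multiple testing across its terms. Conditional on a
significant comparison, non-significant interactions (p > 0.1) are removed
iteratively — all non-significant interactions of the same and highest
order simultaneously per step, never main effects — to make lower-order
terms interpretable (`prune_interactions()`; the trace of every step is
returned). Terms are ordered deterministically (interaction order, then
lexicographic), so traces are reproducible.

Design decisions worth calling out:

* **Maximum likelihood and LRTs throughout.** Gaussian families use
  `lme4::lmer` with `REML = FALSE`, the Poisson family `lme4::glmer`, the
  beta family `glmmTMB`. Significance of individual terms uses drop-one
  likelihood-ratio tests for every family rather than Satterthwaite
  approximations for the Gaussian ones; a single LRT policy is simpler and
  asymptotically equivalent.
* **Reduced default random structure.** Intercepts for family, parent and
  session-in-family, an uncorrelated register slope within family, plus
  word and vowel-category intercepts where the response is token- or
  category-level. Maximal slope-with-correlation structures routinely
  produce singular fits that then have to be simplified anyway; any
  structure can be supplied via `model_spec(family, random = ...)`.
* **Beta boundary handling.** Distinctiveness values of exactly 0 or 1
  are shrunk by `(y(n-1) + 1/2)/n` before the logit-link fit, only when
  boundary values occur. The beta precision is a single fixed dispersion
  parameter (modelled dispersion is out of scope).
* **Convergence is surfaced, never swallowed.** Fits carry `converged`
  and `singular` flags and optimizer messages; a negative full–null
  statistic is reported as a convergence symptom. Fits default to bobyqa
  without the expensive finite-difference derivative check (the check
  roughly doubles fit time and its warnings are dominated by boundary
  variance components in simulation work); the optimizer's own return
  code is still inspected.
* **Parametric bootstrap and leave-one-out stability** are available
  (`bootstrap_ci()`, `stability_leave_one_out()`) but optional: both are
  refit-heavy and meant for final models, not simulation loops.

## The synthetic cohort generator

`generate_cohort()` emulates the design of a longitudinal register study:
families enrolled at a first session (child age about 182 days) and
followed at roughly 3-month intervals to about 542 days; both registers
recorded at every session from one parent, with mothers predominant at the
first and last two sessions and fathers at sessions two and three
(parental-leave scheduling); monotone attrition of about 3.3% per
follow-up (13% across five sessions); about 62% girls; counterbalanced
recording order fixed within family.

Ground truth is injected on each measure's modelling scale
(`effect_config()`): semitone shifts for pitch and pitch range, a log rate
ratio for articulation rate (syllable counts are Poisson given phonation
time, so family 3's likelihood matches the generating process), a log-ms
shift for duration, a multiplicative expansion of IDS category means away
from the vowel-space centroid, and a multiplicative inflation of IDS
within-category standard deviations (which multiplies expected variability
by its square). Age slopes and mother–father offsets are per-measure,
per-register named vectors. With every effect at its neutral value the two
registers are exchangeable by construction.

Formant clouds are bivariate Gaussian with diagonal covariance — the
variability formula `π σF1 σF2` is then exact on truth — and fathers'
formants are scaled by 0.85 to reflect the longer male vocal tract. The
default inventory means are plausible values for a Norwegian-style
nine-long-vowel system chosen by the implementer; they are fixtures, not
estimates of any real speaker population. Phrase F0 is generated directly
as min/mean/max summaries (the pipeline consumes only those three numbers,
so full contours would add nothing testable), and audio fixtures are
harmonic tones over near-zero noise floors — the phonation detector uses
only energy, so spectral realism is unnecessary. None of this emulates
forced-aligner errors, manual boundary adjustment, or content-driven
prosody; passing tests therefore validate the pipeline's arithmetic and
inference protocol, not its robustness to real-world alignment noise.

## Validation problem sizes

The package's own acceptance tests run at deliberately scaled-down sizes:
type-I calibration uses 200 neutral cohorts of 50 families × 5 sessions
with 10 phrases per recording (about 4,700 phrases each; the study-scale
default is 36 phrases per recording), chosen as the smallest replicate at
which the χ² reference for the 5-df full–null test is accurate — at very
small per-recording counts the test drifts a few points from nominal in
either direction, a finite-sample property of ML likelihood-ratio tests,
not a bug. Effect recovery averages 20 seeded cohorts of 60 families with
injected effects of +2.5 st (pitch), −0.104 (log rate ratio), +0.10 (log
duration) and ×2 (variability inflation, i.e. ×4 ≈ +1.386 on the log
scale). `scripts/acceptance.R` re-runs the same computations from scratch
at every invocation and reports the recovered values.

## Known limitations

* The TextGrid reader supports interval tiers only (point tiers are out of
  scope for this pipeline) and identifies the word/phone tiers by name.
* The phonation detector is energy-based by design; breathy or very quiet
  voiced stretches below the −25 dB floor count as silence.
* Distinctiveness treats F1 and F2 in raw Hz; no per-dimension
  standardization or perceptual scaling is applied, matching the plain
  sum-of-squares definition.
* Model 8's beta fit uses fixed precision; responses collapsing onto the
  boundaries beyond the shrinkage adjustment will misbehave.
* The generator's attrition is monotone dropout; intermittent missed
  sessions (skip one, return later) are not modelled.
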