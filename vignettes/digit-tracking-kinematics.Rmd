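---
title: "Digit-tracking reading kinematics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digit-tracking reading kinematics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method in brief

Digit-tracking turns a touchscreen into a crowding-free reading display:
text is shown through a Gaussian blur (standard deviation 20 px) that mimics
the low resolution of the peripheral retina, and a window around the child's
finger shows the original sharp text, so only the pointed-at letters reach
foveal vision. Because the finger must travel where the eyes need to read,
the 60 Hz finger trace is a proxy for the scanpath, and eye-movement-style
analysis applies: the trace is segmented into *digital fixations* (slow
phases) and *digital saccades* (fast phases), and their kinematics — fixation
duration, saccade length and speed, the proportion of regressive (leftward)
saccades, and the landing position of the first fixation on each word —
index decoding skill and its growth over training.

This package implements that pipeline end to end, together with the study
design around it: pseudoword training material, session plans, reading
assessments with their scoring rules, the good/poor decoder median split,
and the linear mixed models relating kinematics to decoding skill. A seeded
simulator generates cohorts with known parameters, so the whole chain is
validated by parameter recovery rather than by reference outputs.

```{r, eval = FALSE}
library(digitrace)
r <- cohort_parameter_recovery(seed = 1)
r$speed_gap          # good - poor contrast from the mixed model
r$mean_fixation_duration_ms
```

## Segmentation model

For each subject and session, every inter-sample speed (Euclidean pixel
displacement, converted to mm via the pixel pitch, divided by the
inter-sample interval) is pooled across trials; the *median of the strictly
positive speeds* is the individual threshold. Samples at or below the
threshold are "slow", faster samples are "fast"; maximal slow streaks are
digital fixations, maximal fast streaks digital saccades. A fixation's
position is the barycenter of its member samples, its duration the time span
of those samples; a saccade's length is the distance between the flanking
fixation barycenters (mm), its speed the mean of its member speeds (mm/s),
and it is progressive only if the X of its last sample exceeds the X of its
first (ties count as regressive). A slow streak whose member spread reaches
5.8 px in X or 6.4 px in Y is split greedily, left to right, at the first
violating sample.

Numerical choices worth stating explicitly:

* **Ties at the threshold** are slow ("at threshold" is not "moving fast"),
  and the comparison uses a relative tolerance of `1e-8` so that speeds equal
  to the threshold up to floating-point rounding classify as ties. Exact ties
  are not a corner case here: on a regular sampling grid the median is itself
  one of the observed speeds.
* **The first sample** of a trial (and the first touch after a finger lift)
  carries no speed and joins the class of the following sample.
* **Finger lifts** break streaks; lifted samples belong to no event. No
  minimum fixation duration is imposed (a configurable floor exists,
  default 0).
* **Saccades at the trial edges** (no flanking fixation on one side) report a
  missing length but keep their speed and direction.
* **Saccade-free trials** report a *missing* regressive proportion, not 0,
  so aggregates are not dragged toward zero.

The segmenter is verified against a brute-force label-then-scan classifier
(an independent loop-based implementation) on a thousand random short
trajectories, and the whole quantity chain is unit-checked against hand
arithmetic (e.g. a 3-4-5 pixel step at 60 Hz and 0.135 mm/px is 40.5 mm/s).

## Units and the pixel pitch

Logs store positions as percent of screen; (100, 100) maps to the full
pixel extent. All millimetre quantities depend on the pixel pitch, which the
logs do not contain. The default, 0.135 mm/px, is the pitch of a 12.3-inch
3:2 panel at 1920 x 1280 — a plausible tablet of the study's class — and is
a configuration knob (`screen_geometry()`), not a measurement. Thresholding
is invariant to monotone unit changes (tested), so the pitch scales reported
lengths and speeds without changing the segmentation.

## Word-level measures

Words are laid out monospaced, so character positions are affine in letter
index; the landing position of the first fixation on a word is
`(barycenter_x - origin_x) / char_width`, a continuous value with the first
letter spanning [0, 1). Fixations belong to the word whose padded box
contains their barycenter; the padding — half the inter-word space
horizontally, one line height vertically — is this package's choice, since
word regions of interest have no canonical definition. Landing values may
slightly exceed `[0, n_chars]` under padding and are clipped for reporting
(the raw value is available). Words of 1-6 letters are "short", 7-11
"long". Group density maps of first landings use a Gaussian kernel with
bandwidth 0.4 times the nrd0 reference rule
`0.9 min(sd, IQR/1.34) n^(-1/5)`, and are scaled by group size so unequal
groups remain comparable; the 0.4 factor and the scaling are protocol
constants, and the exact nrd0 rule is stated so other implementations can
match bit for bit.

## Assessments and the decoder split

The decoding list is scored with a discontinuation rule (stop after 5
consecutive errors, 85-item ceiling); timed texts yield accuracy (percent of
attempted items correct) and fluency (items correct per minute of the time
limit); training outcomes are pre/post gains on the native scale. Decoder
groups come from a median split of the post-training decoding score:
strictly above the median is "good", strictly below "poor", and ties follow
a configurable rule (default "poor", recorded on the output) because the
split is otherwise undefined for ties. The real instruments are copyrighted;
the package ships no test content and instead simulates response vectors
with matching structure (item counts, time limits, the run rule).

## Mixed models

Two model families are encoded. Reading change:
`gain ~ modality * phase + age + 8 cognitive covariates + (1 | subject)`;
finger kinematics:
`response ~ decoding * session * phase + (1 | subject) [+ (1 | word)]`,
with session categorical (the per-session contrasts of interest require it).
Tests use Satterthwaite degrees of freedom via lmerTest; estimates are
reported unstandardised, in native units, with Wald 95% intervals. Treatment
coding uses references "paper", phase 1, "poor", session 1 so printed
contrasts read in the study's direction. REML is on for final estimates and
must be off (`REML = FALSE`) for AIC/BIC comparison across fixed structures
— the choice is recorded on every fit. Effect sizes are semi-partial
R-squared values in the Nakagawa-Schielzeth/Johnson variance-ratio style:
the variance of a term's contribution to the linear predictor over the total
model variance (fixed + random intercepts + residual). With correlated
predictors such per-term numerators are not a strict decomposition; in the
balanced designs generated here the model-level value bounds every term
value (tested). No multiple-testing correction is applied anywhere, and
reports should say so. Descriptive two-group comparisons gate on Shapiro-
Wilk at alpha 0.05 in each group: both normal, Welch t; otherwise Wilcoxon
rank-sum, two-sided.

## The simulator: what it emulates, and what it does not

`simulate_trial()` inverts the segmentation model: left-to-right first
fixations on each word, with the first landing drawn around 1.60 characters
(short words) or 3.14 characters (long words, SD 0.3); rightward
refixations at a Poisson rate per character; fixation durations Gaussian
(SD 100 ms, floor 120 ms); saccades with a symmetric triangular speed ramp
(mean speed approximately half the peak — saccade-speed recovery depends on
this shape, which is why it is fixed); and each saccade independently
regressive with probability `p_regressive`. An alternative regression
scheme — insert a leftward excursion and an unconditional return — would
make the realised regressive fraction converge to `p/(1+p)` rather than
`p`; the independent-direction scheme was chosen so the generative
probability is itself the recoverable quantity.

Fixation jitter is the one deliberately stylised component. Nonzero jitter
steps have a *constant* magnitude of 0.8 px/frame (6.48 mm/s at the default
pitch), occur on 60% of frames, and the walk folds back into a ±2.4 px box.
The constant magnitude is chosen analytically, before any testing, so that
the pooled median speed of every subject-session lands exactly on the
jitter speed: jitter steps then outnumber saccade samples among nonzero
speeds, the threshold is identical across decoder groups (no spurious
group differences in the measurement operator), ties classify as slow (no
shattered fixations), and every ramp sample stays clearly above threshold
(intact saccades). Real finger traces have none of this regularity; passing
recovery tests therefore demonstrates that the pipeline is a faithful
inverse of this generative model under realistic magnitudes, not that it is
robust to arbitrary tablet noise.

Default group profiles place the printed group contrasts in the generator:
good minus poor saccade mean speed +13.57 mm/s (73.57 vs 60), fixation
duration -68.6 ms around a 400 ms mean (365.7 vs 434.3), equal regression
probability 0.25 and equal landing means, refixation rates 0.04 vs 0.08 per
character (this, not an explicit amplitude gap, lengthens good decoders'
saccades), assessment success 0.85 vs 0.60. Session drift multipliers are
normalised to mean 1 so phase-pooled means equal the profile means; phase
offsets exist as knobs but default to zero, keeping the pooled generative
values the reference truth for recovery. Each cohort is a pure function of
its configuration and seed.

## Problem sizes and tolerances

The validation suite uses cohorts of 2 x 10 subjects, 6 sessions and 3
five-word sentence trials per session (about 80,000 samples per cohort),
50 seeded replicates for recovery and 12 null cohorts x 4 label
permutations for calibration — sizes at which the recovery estimators'
Monte-Carlo error is well inside the asserted bands (sign agreement >= 95%,
speed-gap median within 20%, duration and landings within 10%, pooled
regressive proportion in [0.20, 0.30], density integrals within 5%, null
CI coverage >= 85%). These are the package's chosen study conditions;
`cohort_config()` scales all of them.

## Known limitations

* Single-line stimuli; no return sweeps, no proportional fonts, no
  syllable-level regions of interest.
* The simulator does not model the closed loop between the unblur window
  and the finger (the display is not simulated during trajectory
  generation), nor biomechanics of finger motion.
* French syllabification is not automated: decodability takes a
  caller-supplied grapheme segmentation.
* Dropped frames are flagged by validation, never repaired.
* The semi-partial R-squared definition is the variance-ratio form stated
  above; other definitions (e.g. Wald-based) give different values for the
  same fit.
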