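# digitrace

Reading acquisition research with the **digit-tracking** paradigm: text on a
touchscreen is Gaussian-blurred (σ = 20 px) except in a window under the
child's finger, so the finger must travel where the eyes need to read and
the 60 Hz finger trace proxies the gaze path. Crowding from parafoveal
letters — a major obstacle for beginning readers — is suppressed, and the
recorded trajectories become an eye-movement-style measure of decoding
skill.

The package is aimed at researchers analysing such touchscreen reading data
(or planning such a study). It provides:

* **Stimulus preparation** — seeded pseudoword catalogues
  (20 monosyllabic + 60 bisyllabic + 40 trisyllabic items per phase),
  session trial plans, decodability checks (> 60% of phonemes taught),
  monospace text layout with word geometry, Gaussian blur and the
  finger-contingent unblur window.
* **Trajectory ingestion** — a CSV/JSON-lines log schema
  (percent-of-screen coordinates at 60 Hz) with validation, and conversions
  between percent, pixel and millimetre frames.
* **Event segmentation** — the study's rule, exactly: per subject-session,
  the median of all strictly positive speeds is the threshold; maximal
  slower streaks are *digital fixations* (barycenter position, duration,
  with a 5.8/6.4 px dispersion split), maximal faster streaks are *digital
  saccades* (length between flanking barycenters in mm, mean member speed
  in mm/s, progressive iff the X coordinate advances).
* **Reading measures** — first-fixation landing position in continuous
  character units (first letter spans [0, 1)), short (1–6 letters) vs long
  (7–11) word classes, per-word fixation counts, and group density maps
  smoothed with 0.4 × the nrd0 bandwidth `0.9·min(sd, IQR/1.34)·n^(−1/5)`
  and scaled by group size.
* **Assessment scoring** — discontinuation lists (stop after 5 consecutive
  errors, 85-item ceiling), timed-text accuracy and per-minute fluency,
  pre/post change scores, and the good/poor decoder median split.
* **Statistics** — the study's linear mixed models
  (`gain ~ modality*phase + covariates + (1|subject)`;
  `kinematics ~ decoding*session*phase + (1|subject) [+ (1|word)]`) with
  Satterthwaite degrees of freedom, unstandardised effect sizes with Wald
  CIs, semi-partial R² (Nakagawa–Schielzeth/Johnson variance-ratio form),
  AIC/BIC/RMSE model comparison, and Shapiro-gated t/Wilcoxon group
  comparisons.
* **A cohort simulator** — seeded finger trajectories and assessment
  responses with known group differences, so every stage is validated by
  parameter recovery.

## Worked example

Simulate one good-decoder trial over a five-word pseudoword sentence,
segment it with its median-speed threshold, and read off the kinematics:

```r
library(digitrace)

geom  <- screen_geometry()                  # 1920x1280, 60 Hz, 0.135 mm/px
stim  <- default_sentence_set(geom)[[1]]    # "bora muti faderont lipa vomirade"
trial <- simulate_trial(good_reader_profile(), stim, geom, seed = 42)

sp  <- compute_speeds(trial, geom)
th  <- median_speed_threshold(sp)           # 6.48 mm/s for this trace
seg <- segment_trajectory(sp, th, geom)
trial_kinematics(seg$fixations, seg$saccades)
#>   n_fixations mean_fixation_duration_ms n_saccades n_progressive n_regressive
#> 1           7                    426.19          6             6            0
#>   proportion_regressive mean_saccade_length_mm mean_saccade_speed_mm_s
#> 1                     0                 11.313                  68.356

word_fixation_metrics(seg$fixations, stim$word_boxes)[, 1:5]
#>       word n_chars length_class first_landing n_fixations
#> 1     bora       4        short          2.05           1
#> 2     muti       4        short          1.65           1
#> 3 faderont       8         long          3.11           2
#> 4     lipa       4        short          1.51           2
#> 5 vomirade       8         long          3.04           1
```

Seven fixations averaging ~426 ms, six forward saccades around 68 mm/s, and
first landings near the second letter of short words and the third letter of
long words — the landing-position word-length effect the paradigm is built
to measure. `simulate_cohort()` scales this to a full crossover cohort,
`analyze_cohort()` runs assessments → median split → segmentation → metrics,
and `fit_kinematics_model()` fits the decoding × session × phase mixed
model.

## Layout

```
R/               implementation (geometry, stimuli, trajectory IO,
                 segmentation, reading metrics, assessment, models,
                 simulator, pipeline)
tests/testthat/  unit, property and acceptance suites
scripts/         acceptance.R
vignettes/       methods vignette: models, parameters, design choices
```
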