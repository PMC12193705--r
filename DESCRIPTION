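Package: digitrace
Title: Digit-Tracking Reading Kinematics: Stimuli, Trajectory Segmentation and Mixed-Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying early reading with the digit-tracking paradigm,
    in which text is shown Gaussian-blurred on a touchscreen and unblurred
    locally under the child's finger so the finger trace proxies the gaze path.
    The package builds crowding-free training stimuli (pseudoword catalogues,
    session plans, blurred frames with a finger-contingent window), reads and
    validates 60 Hz finger-trajectory logs, segments them into digital
    fixations and saccades with a per-subject median-speed threshold, derives
    word-level reading measures (first-fixation landing position, refixations,
    kernel density maps), scores reading assessments (discontinuation rules,
    accuracy, fluency, change scores, median split into good and poor
    decoders), and fits the study's linear mixed models with Satterthwaite
    degrees of freedom, semi-partial R-squared and AIC/BIC/RMSE comparison.
    A seeded cohort simulator generates finger trajectories and assessment
    responses with known group differences so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
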