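Package: crossgaze
Title: Gaze and Psychophysics Analysis for Pedestrian Road-Crossing
    Discrimination Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses two-interval forced-choice experiments in
    which observers at a virtual roadside discriminate the speed or
    time-to-arrival of approaching vehicles while their gaze is tracked.
    Provides constant-velocity scene kinematics and dynamic areas of
    interest, a synthetic observer generating pursuit-plus-catch-up-saccade
    gaze traces and noisy-ideal-observer responses, velocity/acceleration
    threshold saccade detection with blink handling and exclusion rules,
    per-trial gaze metrics (pursuit gain from 3D angular velocities, AOI
    position deviations, saccade statistics, MAD/double-MAD outlier
    screening), maximum-likelihood cumulative-normal psychometric fitting
    (JND, PSE, Weber fraction, deviance goodness of fit, interval bias),
    dominance analysis of cue use in logistic regression, task/observer
    classification with leave-one-subject-out and k-fold cross-validation
    plus permutation testing, and hierarchical logistic models of
    trial-level performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    lme4,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
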