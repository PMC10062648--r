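Package: emostim
Title: Validation of Emotional Short-Video Stimuli and EEG Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating affective audio-visual stimuli from Likert
    rating scales and verifying their elicitation effect from EEG recordings.
    Implements the success-index scoring rule (sum of within-pool z-scores of
    hit rate and target-emotion intensity), Yates-corrected chi-square and
    t-tests for group comparisons, the three-way mixed (split-plot) ANOVA with
    partial eta squared and Bonferroni-corrected simple effects, a differential
    entropy feature pipeline for 14-channel EEG (band-pass/notch filtering,
    artifact screening, 1-second epoching, five-band features), and an
    11-classifier emotion-recognition harness with stratified 8:2 evaluation.
    Seed-deterministic generators simulate both rating tables and multichannel
    EEG with planted group effects and condition-dependent band power, so every
    pipeline stage is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    nnet,
    rpart,
    randomForest,
    e1071,
    xgboost,
    class,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
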