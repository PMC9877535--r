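Package: vmreach
Title: Kinematic Scoring and Brain-Behavior Modelling of Decoupled Visuomotor Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing centre-out sliding reaches under standard and
    non-standard (plane-change and feedback-reversal) visuomotor mappings.
    Provides a synthetic cohort generator with minimum-jerk trial kinematics and
    matched structural/diffusion brain-measure tables; dual-pass Butterworth
    filtering and 10%-of-peak-velocity movement segmentation; per-trial error
    classification, direction-reversal coding and the standard timing, accuracy
    and precision outcome measures; composite z-scores with Cronbach's alpha;
    intracranial-volume adjustment of regional volumes by the control-fit
    residuals method; and moderated multiple regression with simple-slopes
    analysis and Holm family-wise correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
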