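Package: gaitonset
Title: Real-Time Motion-Onset Recognition for Gait-Rehabilitation Activities
    from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recognise the onset of eight gait-rehabilitation
    activities (sit-to-stand, stand-to-sit and their settling phases, walking,
    turning, quiet standing and sitting) from three body-worn inertial
    measurement units (sternum and both thighs) sampled at 100 Hz. Includes a
    labelled synthetic-cohort generator emulating a chair-rise/walk/U-turn
    protocol, magnetometer-free quaternion orientation fusion (strap-down
    integration with accelerometer tilt correction), sliding-window
    time-domain feature extraction with majority-vote labelling, SVM-based
    recursive feature elimination, five classifier families including a
    single-hidden-layer neural network trained by scaled conjugate gradients,
    leave-one-participant-out cross-validation with per-class metrics and
    ANOVA/Tukey-Kramer model comparison, and a sample-synchronous streaming
    inference engine whose decisions match the offline classifier exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    rpart,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
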