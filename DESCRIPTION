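Package: bcinav
Title: Simulation and Analysis of a Forward/Backward Motor-Imagery EEG
    Brain-Computer Interface
Version: 0.1.0
Authors@R:
    person("bcinav", "maintainers", email = "bcinav@example.org",
           role = c("aut", "cre"))
Description: Tools to study a two-command (move forward / move backward)
    motor-imagery brain-computer interface recorded from three EEG channels
    (C3, Cz, C4). Provides a calibrated synthetic-EEG generator with
    lateralized post-imagery beta event-related synchronization (ERS),
    Butterworth band-filtering and amplitude-based artifact rejection,
    band-power ERD/ERS time courses, periodogram PSD and interhemispheric
    asymmetry-ratio features, Burg autoregressive and ARX feature models with
    AIC order selection, diagonal LDA and linear SVM classifiers under
    stratified 10-fold cross-validation, and an online threshold-based
    neurofeedback simulator with run-wise learning-curve summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
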