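Package: wristrigidity
Title: Quantitative Wrist Rigidity Assessment from Intraoperative Gyroscope Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal processing and calibration modelling for wearable
    gyroscope assessment of wrist rigidity during deep brain stimulation
    (DBS) surgery. Converts raw inertial counts to angular velocity,
    isolates passive wrist-flexion arcades, extracts per-window features
    (mean flexion velocity, mean peak velocity, cogwheel-artefact count),
    evaluates a catalogue of scalar signal descriptors, and fits
    second-order polynomial calibration curves that map a descriptor to
    the percentage of rigidity improvement under stimulation.  Includes
    leave-one-out cross-validated training error, a tolerance-based
    accuracy report, a baseline-severity (UPDRS) gated multi-model, a
    synthetic surgical-session simulator for end-to-end validation, and a
    command-line interface covering simulate / train / classify /
    evaluate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
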