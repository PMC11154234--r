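Package: hyperhrv
Title: Cardiorespiratory Heart-Rate-Variability Analysis of Hyperbaric Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the cardiorespiratory response to hyperbaric
    chamber exposure from multi-lead ECG alone. Implements ECG-derived
    respiration (R-wave up-slope, down-slope and angle series), respiratory-rate
    estimation by peaked-conditioned spectral fusion, instantaneous heart rate
    from an integral pulse frequency modulation model, decomposition of heart
    rate variability into respiration-driven and residual components by
    orthogonal subspace projection, stage-relative statistics, leave-one-out
    wrapper feature selection over four classifier families, and an
    anomalous-subject detector based on misclassification accumulation. A
    synthetic-cohort generator with full ground truth makes every stage of the
    pipeline testable without access to chamber recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
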