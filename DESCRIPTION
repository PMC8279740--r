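Package: mirrorpop
Title: Single-Unit Waveform Classes, Population Decoding and Mutual
    Modulation Analysis for Action Execution-Observation Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for extracellular single-unit recordings from
    cortical grasping areas during action execution and observation
    (Go/No-Go reach-to-grasp tasks). Builds normalized average spike
    waveforms and extracts trough-to-peak and repolarization features,
    clusters units into cell classes with a diagonal-covariance Gaussian
    mixture selected by BIC, labels units as facilitated or suppressed with
    a sliding-window t test and consecutive-bin rule, decodes task
    variables from pseudo-populations with a Poisson naive Bayes classifier
    and mutual-information time courses with onset-latency estimation, and
    computes the time-resolved Mutual Modulation Depth (MMD) index coupling
    execution and observation activity. Includes an inhomogeneous-Poisson
    synthetic-data generator with planted ground truth so the whole chain
    is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
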