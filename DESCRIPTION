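Package: erpsig
Title: Condition-Specific Prediction Signatures in Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects condition-specific signatures in event-related potentials
    (ERPs) recorded over sensorimotor cortex during action observation.
    Implements a hierarchical per-subject pipeline: zero-phase band-pass
    filtering, re-referencing to averaged auricular electrodes, epoch
    segmentation around event markers, amplitude-threshold artifact rejection
    on frontal channels, per-condition epoch averaging, k-means clustering
    (k = 3) of the twelve averaged waveforms of each four-electrode set, exact
    tests of independence between cluster label and experimental condition for
    every condition pair, and Benjamini-Hochberg false-discovery control.
    Includes a synthetic ERP-experiment generator with known ground truth
    (event-locked templates, autoregressive noise, injectable artifacts) so
    that every stage of the pipeline can be validated end to end without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
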