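Package: gazeway
Title: Gaze Time Headway Estimation and Decomposition for Simulated Driving
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing where drivers look along the road ahead in
    fixed-base driving-simulator experiments. Estimates a gaze time headway
    signal by mapping screen-coordinate gaze onto an arc-length parameterised
    track midline, decomposes the pooled headway signal into guiding-fixation,
    bend-entry-fixation and noise components with a fixed-slope regression
    mixture model fitted by expectation-maximisation, parses the gaze trace
    into tracking episodes and saccades with penalised segmented linear
    regression, and compares driving modes with a hierarchical Bayesian model.
    Includes a synthetic sawtooth-gaze generator with full ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    rjags,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
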