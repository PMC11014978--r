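Package: rnaptransit
Title: Kinetics of RNA Polymerase Transit Through Protein Roadblocks
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-molecule tether-extension records of
    transcription elongation through DNA-bound protein roadblocks. Provides a
    six-state kinetic Monte Carlo model of roadblock transit (backtracking,
    recovery, spontaneous roadblock dissociation and active dislodging), exact
    total-variation step fitting of noisy extension traces, dwell-time
    histogram construction and linear trace alignment, extraction of
    roadblock-associated pauses with right-censoring, censored exponential and
    exponential-mixture lifetime fitting, and simulation-based fitting of the
    kinetic model to condition-grouped pause-time distributions. A synthetic
    trace generator with ground-truth annotations supports end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
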