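Package: ffreport
Title: Simulation and Analysis of Feature Frequency Report Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying explicit access to feature-distribution
    representations in ensemble perception. Generates feature frequency
    report (FFR) sessions on a circular 48-hue color wheel with Gaussian,
    uniform and bimodal exemplar distributions, simulates sub-sampling and
    veridical-noisy observers, analyzes response curves by folding and
    paired comparisons, fits two-segment (broken-line) regressions with
    break-point estimation and Davies tests, computes an exact likelihood
    for the sub-sampling observer, fits it by maximum likelihood, and runs
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
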