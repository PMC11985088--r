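Package: chanscreen
Title: Single-Channel Trace Idealization and Yeast Complementation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain from raw single-channel current recordings to
    functional channel parameters and on to yeast-growth correlation and
    classification. Provides a continuous-time Markov gating simulator with
    acquisition physics (Gaussian noise, Bessel low-pass filtering, sampling),
    baseline estimation and two-level idealization with a higher-order Hinkley
    jump detector, current-voltage and open-probability relations with unitary
    conductance fits and time-averaged current ("activity") summaries, and
    OD600 growth quantification with WT-anchored quadrant classification,
    Pearson correlation, and multilinear modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
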