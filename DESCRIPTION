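Package: wardmpc
Title: Secure Two-Party Clustering of Nurse-Patient Facing Times from RTLS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.invalid",
    role = c("aut", "cre"))
Description: Builds nurse-patient facing-time frequency tables from zone-level
    real-time locating system (RTLS) traces split between a hospital (patient
    tags) and a labour union (nurse tags), and clusters nurses with an
    integer-only k-means variant using exact rational centroids.  Both phases
    run either in the clear or as a two-party secure computation over additive
    secret shares in a prime field (trusted-dealer Beaver multiplication and
    statistically masked comparison gates), with bit-for-bit agreement between
    the two execution modes.  Includes a synthetic RTLS ward simulator, a
    circuit budget planner, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
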