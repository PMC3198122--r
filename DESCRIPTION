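Package: seamsim
Title: Seamless Phase II/III Adaptive Trial Simulation with Sequential
    Dose Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for seamless phase II/III clinical trial designs in
    which an early trichotomous outcome drives a truncated sequential
    elimination procedure among candidate dose arms, clinical promise and
    futility rules gate continuation, and a group-sequential phase III
    tests two co-primary hypotheses on a trichotomized clinical endpoint
    with continuity-corrected pooled z-tests and the Holm step-down
    procedure. Provides constrained random generation of null-hypothesis
    outcome distributions (joint distributions of the early and clinical
    endpoints subject to marginalization and clinical monotonicity
    constraints), vectorized Monte-Carlo estimation of selection operating
    characteristics, and experiment-wise type I error studies in both
    group-sequential and fixed-sample-size modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
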