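Package: natfert
Title: Individual-Level Natural-Fertility Simulation and Likelihood-Free
    Estimation
Version: 0.1.0
Authors@R:
    person("natfert", "developers", email = "natfert@example.org",
           role = c("aut", "cre"))
Description: Monthly discrete-time microsimulation of reproductive histories
    in natural-fertility populations (lognormal age at marriage, a
    two-parameter Bernstein-polynomial age profile of fecundability, fixed
    nine-month gestation and a post-partum amenorrhea period), together with
    a likelihood-free estimation pipeline: uniform priors, approximate
    Bayesian computation by rejection on the Euclidean distance between
    age-specific fertility rate schedules, and random-forest regression
    adjustment of the accepted draws. Includes a Gamma-frailty extension for
    heterogeneous fecundability, a leave-one-out cross-validation harness
    with the scaled prediction-error statistic, maternity-history ingestion
    with intact-marriage filtering, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
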