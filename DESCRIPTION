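Package: nestchoice
Title: Collective Nest-Site Selection Models with Heterogeneous Acceptance Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic mean-field and finite-population stochastic models of
    collective nest-site selection by ant colonies in which individual workers
    carry heterogeneous acceptance thresholds. Provides a nine-compartment
    ordinary differential equation model with forward-Euler integration, an
    exact event-driven (Gillespie) agent-based counterpart with a discrete-time
    cross-validation engine, a Monte-Carlo experiment harness for quantifying
    speed-accuracy trade-offs (time-to-quorum versus choice accuracy and their
    Pearson correlation), and a multi-nest variant measuring speed-cohesion
    trade-offs via an entropy-based cohesion index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
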