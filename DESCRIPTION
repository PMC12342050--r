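Package: cellsizer
Title: Stochastic Hybrid Models of Single-Cell Size Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling single-cell size homeostasis as a stochastic
    hybrid system: deterministic exponential growth in cell size punctuated by
    random division events whose hazard scales as a power law of size, with
    noisy (beta-distributed) size partitioning between daughters. Provides
    exact closed-form steady-state moments (mean, noise, skewness) for the
    adder regime and for multi-stage cell-cycle models, a derivative-matching
    moment closure for sizer-like power-law hazards, an exact event-driven
    lineage simulator based on closed-form inverse-hazard sampling, the
    moment dynamics of the non-homeostatic size-independent division rate,
    and moment-matching estimation of model parameters from observed cell
    size samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
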