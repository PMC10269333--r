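Package: aedskit
Title: Accelerated Enveloping Distribution Sampling for Alchemical Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for accelerated enveloping distribution sampling (AEDS)
    free-energy calculations on analytically tractable toy systems. Builds
    multi-end-state reference Hamiltonians with energy offsets and a harmonic
    boosting potential, searches acceleration parameters (energy offsets via
    memory-decayed exponential averaging, boost bounds from barrier crossings
    and end-state fluctuations), probes fractional occupancy of switchable
    molecules (coupled water versus non-interacting dummy), and couples AEDS
    to thermodynamic integration (TI-AEDS) with exponential-averaging
    reweighting, analytic restraint corrections, and thermodynamic-cycle
    closure diagnostics. All estimators are testable against exact or
    quadrature oracles on bundled one- and two-coordinate fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
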