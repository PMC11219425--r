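Package: protistNR
Title: Numerical and Thermal Response Analysis for Protist Microcosm
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits threshold numerical-response curves to per-well growth
    rates of bacterivorous protists, derives the maximum physiological
    mortality rate (growth at zero food) with Monte-Carlo uncertainty
    propagation, fits Lactin-2 thermal performance curves and extracts
    thermal traits (optimum temperature, critical thermal limits, thermal
    safety margin), regresses mortality on temperature, and evaluates
    simple grazing-pressure scenarios. Includes a well-level microcosm
    campaign simulator for parameter-recovery studies and a packaged
    reference analysis for the Colpidium kleini growth study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    MASS,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
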