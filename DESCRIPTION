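Package: holophos
Title: Kinetic Analysis of Substrate-Specific Dephosphorylation by
    PP1 Holophosphatase Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative enzymology of eIF2-alpha
    holophosphatase assays read out on Phos-Tag gels: ratiometric
    conversion of band-intensity pairs to substrate and product
    concentrations, first-order decay fitting and initial velocities from
    the integrated rate equation, specificity-constant-proportional
    slopes from velocity-versus-substrate regressions, fold-change ratios
    with Fieller confidence limits and a wildtype-normalised specificity
    factor, hyperbolic G-actin dose-response (EC50) fitting, cellular
    substrate-concentration estimation from quantitative immunoblots or
    molecule counts, and seeded synthetic-data generators that make every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
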