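Package: dipetkin
Title: Dual-Input Liver FDG Kinetic Modelling with Gravitational Search Fitters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compartmental kinetic analysis of short dynamic
    18F-FDG PET of the liver. Implements the dual-input reversible
    two-tissue-compartment model (hepatic artery and portal vein mixed by
    the hepatic arterial perfusion index), three interchangeable parameter
    estimation engines (bounded nonlinear least squares, the gravitational
    search algorithm, and a dynamic chaotic variant with an inertia-weighted,
    chaotic velocity update), a synthetic two-group cohort generator for the
    16-frame five-minute sampling schedule, and an evaluation layer with
    AIC/BIC fit quality, two-group t-tests and correlated ROC comparison.
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
    pROC,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
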