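Package: ausnmr
Title: Association Constants of Weak Pi-Pi Complexes from Proton-NMR
    Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of proton-NMR titrations of weak 1:1 pi-pi
    acceptor-donor complexes. Fits the 1:1 binding isotherm to per-proton
    upfield-shift data by nonlinear least squares to estimate the
    association constant K and the complexation shift, quantifies the bias
    that additional unspecific shielding (AUS) by excess free donor
    introduces into those estimates via deterministic simulation, compares
    per-proton estimates with a fixed-x (residual-resampling) bootstrap
    with Anderson-Darling normality gating and Bonferroni-corrected
    pairwise tests, and applies slope diagnostics, max-K selection and
    K-order ranking to infer complex stability and stacking geometry. A
    seeded synthetic-titration generator emulates the experimental design
    for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
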