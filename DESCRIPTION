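Package: hexspread
Title: Quantifying Cell-To-Cell Viral Transmission on a Hexagonal Cell Monolayer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of viral spread by cell-free and direct
    cell-to-cell transmission within a monolayer of stationary cells arranged
    on a hexagonal lattice, together with the population-level virus-dynamics
    model family used to analyse such data. Includes a perimeter-fraction
    adjustment term that corrects mass-action cell-to-cell transmission
    kinetics for the decreasing proportion of infected cells able to
    contribute to local spread as infection foci grow, delayed-infectivity
    model variants, Gaussian maximum-likelihood fitting of replicate time
    series, small-sample Akaike model comparison, and profile-likelihood
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
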