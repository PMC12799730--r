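Package: twocodon
Title: Two-Codon Translation Kinetics with Dynamic tRNA Charging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic simulation of a coarse-grained
    model of mRNA translation in which two codon classes (optimal and
    non-optimal) compete for two dynamically aminoacylated tRNA pools.
    Provides a closed-form-backed steady-state solver, ODE time courses,
    exact Gillespie simulation in mean-field and codon-resolved form,
    codon-usage sweeps that locate the expression-maximizing fraction of
    optimal codons, a scaling law for total tRNA abundance, and a
    burst-size to growth-rate conversion for bacteriophage fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
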