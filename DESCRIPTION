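Package: stayltm
Title: Bayesian Linear-Threshold Animal Models for Sow Litter Size and Stayability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multiple-trait linear-threshold animal models by Gibbs
    sampling, for joint analysis of continuous litter-size traits (number
    born alive at parities 1-3) and a binary sow stayability trait modelled
    on the liability scale with the threshold fixed at 0 and the threshold
    trait's residual variance pinned to 1. Includes pedigree utilities
    (validation, renumbering, inbreeding, the numerator relationship matrix
    and its sparse inverse), data-editing rules for sow reproduction
    records (age-at-first-farrowing filters, herd-year-season contemporary
    groups, stayability coding with right censoring), posterior summaries
    of heritabilities and genetic and phenotypic correlations, and a
    synthetic pedigreed-herd generator with liability-linked culling for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
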