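Package: segfam
Title: Complex Segregation Analysis of Binary Traits in Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complex segregation analysis for binary traits in extended
    pedigrees using regressive multivariate logistic models with a latent
    three-state major type (AA/AB/BB). Provides exact pedigree likelihoods by
    variable elimination (Elston-Stewart peeling) over types, single-proband
    ascertainment correction, thirteen named transmission/association models
    (sporadic, Mendelian dominant/recessive/codominant/additive, tau-AB-free,
    environmental, homogeneous general, general, and more), constrained
    maximum-likelihood fitting with multistart, likelihood-ratio and AIC model
    comparison, PED-format input/output, relationship-pair accounting, and a
    genotype-dropping simulator of singly ascertained multiplex families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
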