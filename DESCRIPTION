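Package: stratsim
Title: Simulation-Based Comparison of Population Stratification Corrections for Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates case-control cohorts under controllable population
    structure (discrete, admixed and hierarchical scenarios built from
    Balding-Nichols founder pools and random mating) with a single disease
    susceptibility locus parameterized by prevalence and genotype relative
    risks, applies the main association strategies used to correct for
    population stratification (Armitage trend test, Genomic Control,
    Eigenstrat, principal-component and label adjusted logistic and linear
    regressions, Fisher and Stouffer meta-analyses), and estimates each
    strategy's false positive rate and power by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
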