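Package: ecgc
Title: Environmental Covariate Search Affecting Genetic Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which environmental covariates (meteorological factor by
    growth-stage window) shape genotype-by-environment interactions in
    multi-environment trial data. Genetic correlations between environments are
    estimated with genomic best linear unbiased prediction (GBLUP) and pairwise
    bivariate restricted maximum likelihood, and scanned against linear-kernel
    similarity matrices of candidate environmental covariates. Sensitivities
    (reaction-norm slopes) to detected covariates are mapped by mixed-model
    genome-wide association with false discovery rate control and subsampling
    validation. Includes a power-simulation module based on LKJ-distributed
    correlation matrices and a synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    cluster,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    vcfR,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
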