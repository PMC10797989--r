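Package: holopred
Title: Hologenomic Prediction of Pig Traits from Microbiota and Genomic Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds microbiota covariance matrices (log-transformed,
    centered and scaled OTU counts) and VanRaden genomic relationship
    matrices, fits Bayesian linear mixed models with genomic and/or
    microbiota random effects by Gibbs sampling with scaled-inverse
    chi-square variance priors, and evaluates phenotype prediction
    accuracy under diet-stratified forward cross-validation scenarios
    with a post-hoc analysis of the design factors. Includes a synthetic
    pig-population generator (full-sib pairs split across two diets,
    batch-structured rarefied OTU tables, Mendelian genotypes) so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
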