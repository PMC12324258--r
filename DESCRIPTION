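Package: latentgrm
Title: Structural Equation Modelling of Genomic and Residual Covariance with
    Genetic Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multivariate maximum-likelihood factor models of genomic (A) and
    residual (E) trait (co)variance in samples of unrelated individuals, using
    genome-wide genetic relationship matrices (GRM-SEM). Implements Cholesky,
    Independent Pathway (IP), hybrid (IPC, CIP) and bifactor model families, a
    gene-environment correlation (rGE) extension linking latent genomic and
    residual factors, a data-driven PCA/EFA model-building pipeline,
    standardised variance decompositions (SNP heritability, factorial
    co-heritability, signed A/E/2Cov(A,E) shares), model fit statistics (AIC,
    BIC, SRMR, likelihood-ratio tests; CFI/TLI/RMSEA for phenotypic factor
    models), phenotype rank-normalisation with covariate residualisation,
    PLINK and GCTA-format GRM input/output, and a calibrated synthetic-data
    generator for genotypes and multi-trait phenotypes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
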