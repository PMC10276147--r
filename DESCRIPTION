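Package: mvlassosum
Title: Sparse Multi-Trait Polygenic Risk Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs sparse polygenic risk scores jointly for several
    genetically correlated traits from GWAS summary statistics and a
    reference genotype panel. SNP effects across traits are modelled as
    correlated random effects with per-SNP genetic covariance matrices,
    either constant across the genome or predicted from genomic
    annotations via cross-trait stratified LD-score regression. The
    penalized multivariate objective is minimized by block-wise
    coordinate descent with LASSO or adaptive-LASSO penalties, and the
    penalty parameter is tuned with pseudo summary statistics that split
    full-sample GWAS results into training and validation parts. A
    simulation framework generates correlated genotype panels in LD
    blocks, causal-mixture SNP effects, region-wise summary statistics
    with optional sample overlap, and liability-threshold case-control
    cohorts for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
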