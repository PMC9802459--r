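Package: sdvar
Title: Sex-Differential Expression Variability Analysis for RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose interindividual expression variability
    differs between the sexes (SDV genes) from bulk RNA-seq count matrices.
    Implements joint negative binomial location-scale regression (mean and
    overdispersion each on a log link), nested likelihood-ratio tests,
    permutation calibration of the sex-dispersion coefficient, and the
    surrounding per-tissue pipeline (CPM filtering, upper-quartile
    normalization offsets, PCA-based global outlier removal,
    Benjamini-Hochberg correction, replication analysis). Also provides the
    companion analyses: power/false-positive-rate simulations comparing the
    likelihood-ratio test with Fligner-Killeen and Levene tests,
    permutation-calibrated Fisher's-combined overrepresentation
    meta-analysis across tissues, an eGene depletion test, the tau
    cell-type-specificity index on pseudo-bulk single-cell profiles, a
    forward simulator of sex-specific stabilizing selection, and a
    synthetic-data generator for all required inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    car
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
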