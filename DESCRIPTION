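Package: methmark
Title: Blood DNA Methylation Biomarker Discovery with Dual Machine-Learning Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end discovery pipeline for blood DNA methylation
    biomarkers from Illumina 450K-style beta-value matrices: probe-level
    quality control (detection p-value, bead count, sex-chromosome, SNP and
    cross-reactive filters), per-sample BMIQ normalization of type-II
    probes via three-state beta-mixture fits, empirical-Bayes batch
    adjustment on the logit scale, reference-based leukocyte deconvolution
    by constrained projection, moderated-t differential methylation with
    Benjamini-Hochberg FDR and effect-size filtering, dual marker selection
    by random-forest mean-decrease-Gini importance and CALF greedy
    forward selection with +/-1 weights (permutation significance and
    subsampling stability selection), and covariate-adjusted ROC/AUC
    evaluation with bootstrap confidence intervals. Ships a synthetic-data
    generator with planted effects for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    pracma,
    sva,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
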