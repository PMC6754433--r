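#!/usr/bin/env Rscript
## Stage 6 — evaluation of the top consensus marker.
## Age/sex-adjusted logistic model, AUC of the linear predictor with a
## 2000-replication stratified percentile bootstrap CI, Youden operating
## point, and Pearson correlations of the marker against clinical
## severity (ASSQ-R, ADOS, IQ).

suppressPackageStartupMessages(library(methmark))

ds <- read_dataset("results/02_preprocessed")
cons <- data.table::fread("results/05_markers/consensus_markers.tsv",
                          data.table = FALSE)
top <- cons$probe_id[1]
marker <- ds$beta[top, ]
y <- ds$samples$group

roc <- adjusted_auc(marker, y, covariates = ds$samples[, c("age", "sex")],
                    n_boot = 2000, seed = 104)
cat(sprintf("marker %s:\n", top))
print(roc)

clin <- correlate_clinical(marker, ds$samples[, c("assq_total", "ados_total", "iq")])
print(clin, digits = 3)

dir.create("results/06_evaluation", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(data.frame(marker = top, auc = roc$auc, ci_low = roc$ci_low,
                              ci_high = roc$ci_high, threshold = roc$threshold,
                              sensitivity = roc$sensitivity,
                              specificity = roc$specificity),
                   "results/06_evaluation/roc_report.tsv", sep = "\t")
data.table::fwrite(clin, "results/06_evaluation/clinical_correlations.tsv", sep = "\t")
cat("wrote results/06_evaluation/\n")
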