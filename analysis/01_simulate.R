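#!/usr/bin/env Rscript
## Stage 1 — simulate the study cohort.
## A 450K-like discovery set: 30 adult cases vs 30 matched controls,
## 5000 CpG probes, 10 planted DMPs at delta beta = 0.10, six-cell-type
## leukocyte mixtures, two array batches, and clinical scores at the
## cohort's group means (ADOS 7.0 vs 1.5, ASSQ-R 28.6 vs 6.1).

suppressPackageStartupMessages(library(methmark))

cfg <- generator_config(n_probes = 5000, n_case = 30, n_control = 30,
                        planted_dmp_count = 10, delta_beta = 0.10, seed = 20260929)
g <- generate_dataset(cfg)

dir.create("results/01_data", showWarnings = FALSE, recursive = TRUE)
write_dataset(g$dataset, "results/01_data", truth = g$truth)
write_cell_reference(g$truth$cell_reference, "results/01_data/reference.tsv")

grp <- g$dataset$samples$group == "case"
d <- rowMeans(g$dataset$beta[g$truth$planted_probe_ids, grp]) -
  rowMeans(g$dataset$beta[g$truth$planted_probe_ids, !grp])
cat(sprintf("simulated %d probes x %d samples; %d planted DMPs, mean empirical delta %.4f\n",
            nrow(g$dataset$beta), ncol(g$dataset$beta),
            length(g$truth$planted_probe_ids), mean(d)))
cat(sprintf("ADOS case/control means: %.1f / %.1f; ASSQ-R: %.1f / %.1f\n",
            mean(g$dataset$samples$ados_total[grp]),
            mean(g$dataset$samples$ados_total[!grp]),
            mean(g$dataset$samples$assq_total[grp]),
            mean(g$dataset$samples$assq_total[!grp])))
cat("wrote results/01_data/\n")
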