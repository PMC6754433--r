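#!/usr/bin/env Rscript
## Stage 3 — blood cell composition.
## Houseman-style constrained projection of each sample onto the
## six-cell-type reference, then per-cell-type group comparison.
## The expectation on this cohort: no significant composition
## differences between cases and controls.

suppressPackageStartupMessages(library(methmark))

ds <- read_dataset("results/02_preprocessed")
ref <- read_cell_reference("results/01_data/reference.tsv")
props <- estimate_proportions(ds, ref)
print(props)

tab <- compare_composition(props, ds$samples)
print(tab, digits = 3)
dir.create("results/03_deconv", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(cbind(data.frame(sample_id = rownames(props$proportions)),
                         as.data.frame(round(props$proportions, 6))),
                   "results/03_deconv/cell_props.tsv", sep = "\t")
data.table::fwrite(tab, "results/03_deconv/composition_tests.tsv", sep = "\t")

truth <- jsonlite::read_json("results/01_data/truth.json", simplifyVector = TRUE)
mae <- mean(abs(props$proportions - as.matrix(truth$cell_props)))
cat(sprintf("mean absolute error vs true mixing proportions: %.3f\n", mae))
cat(sprintf("smallest composition-test p: %.3f (%s)\n",
            min(tab$p), tab$cell_type[which.min(tab$p)]))
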