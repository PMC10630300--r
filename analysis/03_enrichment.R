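#!/usr/bin/env Rscript
# Relative abundance and log2 fold change vs the starting pool for the
# full-depth screen from 01, with the replicate sign-consistency score.

library(regenscreen)

lib <- read_library("results/screen/library.tsv")
man <- read_manifest("results/screen/manifest.tsv")
cm <- read_counts("results/screen/counts.tsv")

ab <- relative_abundance(cm, pseudocount = 0.5)
fc <- log2_fold_change(ab, man)
fc <- replicate_consistency(fc, consistency_floor = 0)
print(fc)

out <- write_fold_changes(fc, lib, "results/screen/lfc.tsv")
cat("Wrote results/screen/lfc.tsv\n")

top <- out[order(-out$mean_lfc), ][1:6, c("shrna_id", "gene", "mean_lfc",
                                          "consistency")]
cat("\nTop enriched shRNAs (mean of 5 mice):\n")
print(top, row.names = FALSE, digits = 3)
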