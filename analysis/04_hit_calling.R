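#!/usr/bin/env Rscript
# Two-fold / >= 2-independent-shRNA hit calling with control QC on the
# screen from 01/03. Writes shrna_calls.tsv, gene_hits.tsv and qc_report.tsv.

library(regenscreen)

lib <- read_library("results/screen/library.tsv")
man <- read_manifest("results/screen/manifest.tsv")
cm <- read_counts("results/screen/counts.tsv")

res <- screen_pipeline(cm, lib, man,
                       pseudocount = 0.5, lfc_threshold = 1.0,
                       min_consistency = 0.8, min_shrnas_per_gene = 2L)

write.table(res$shrna_calls, "results/screen/shrna_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$gene_hits, "results/screen/gene_hits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
qc_tab <- rbind(
  data.frame(class = "non_targeting", res$qc$non_targeting),
  data.frame(class = "sentinel_depletion", res$qc$sentinels))
write.table(qc_tab, "results/screen/qc_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

hits <- res$gene_hits[res$gene_hits$gene_call != "none", ]
cat(sprintf("Gene-level hits (>= 2 independent shRNAs at two-fold): %d\n",
            nrow(hits)))
print(hits[, c("gene", "n_shrnas_total", "n_enriched", "n_depleted",
               "gene_call", "support_mean_lfc")],
      row.names = FALSE, digits = 3)
cat("\n")
print(res$qc)
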