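#!/usr/bin/env Rscript
# Simulate the pooled in vivo shRNA screen: 253 guides, 5 mice, 24
# damage-regeneration cycles, deep sequencing of every liver and of the
# starting pool. Writes the library, manifest, counts and planted truth
# under results/screen/, and a FASTQ rendering of the reads (reduced depth,
# for the quantification demo in 02) under scratch/simdata/.

library(regenscreen)

dir.create("results/screen", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch/simdata", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)
sim <- sim_screen(cfg)
write_library(sim$library, "results/screen/library.tsv")
write_manifest(sim$manifest, "results/screen/manifest.tsv")
write_counts(sim$counts, "results/screen/counts.tsv")
write.table(data.frame(shrna_id = sim$library$shrna_id,
                       fitness = unname(sim$truth$fitness[sim$library$shrna_id])),
            "results/screen/truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated screen: %d shRNAs x %d samples, %s reads total\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            format(sim$counts$total_reads, big.mark = ",")))

# FASTQ demo at reduced depth so 02 can exercise demultiplexing + counting
cfg_fq <- sim_config(seed = 1, pool_depth = 2e4, replicate_depth = 2e4)
sim_fq <- sim_screen(cfg_fq, fastq = TRUE, out_dir = "scratch/simdata")
cat(sprintf("FASTQ demo: %s reads written to scratch/simdata/reads.fastq.gz\n",
            format(sim_fq$counts$total_reads, big.mark = ",")))
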