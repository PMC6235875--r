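#!/usr/bin/env Rscript
# Simulate the four-cultivar study: a miniature reference genome, gene
# models, per-cultivar resequencing-style variant calls (two small-seeded,
# two large-seeded cultivars), a 29-tissue FPKM matrix, a DE table and QTL
# intervals, all with planted ground truth. Writes the dataset as standard
# FASTA/GFF3/VCF/BED/TSV files under results/dataset/.

suppressMessages(library(seedvar))

cfg <- synth_config(seed = 42)
ds <- simulate_dataset(cfg)
write_dataset(ds, "results/dataset")

tv <- ds$truth$variants
cat("Simulated", length(ds$genome), "chromosomes of",
    format(cfg$chrom_length, big.mark = ","), "bp and",
    length(ds$genes), "genes.\n")
cat("Planted variants by class:\n")
print(table(tv$class))
cat("Planted expectations:\n")
print(table(tv$expect))
cat("Planted seed-specific genes:", length(ds$truth$seed_specific_genes),
    "; planted candidates:", length(ds$truth$candidate_genes), "\n")
cat("Dataset written to results/dataset/\n")
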