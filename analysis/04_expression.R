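#!/usr/bin/env Rscript
# Screen for seed-specific genes with the tissue-specificity index over the
# 29-tissue FPKM matrix (tau > 0.6 with the expression peak in a seed stage)
# and apply the differential-expression gate (fold change >= 2, q <= 0.05,
# higher in the large-seeded cultivar at S3 and/or S5).

suppressMessages(library(seedvar))

ds <- read_dataset("results/dataset")
spec <- specificity_screen(ds$expression, ds$tissue_meta)
write.table(spec, "results/specificity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Expression patterns over", nrow(spec), "genes:\n")
print(table(spec$pattern))
ss <- spec[spec$pattern == "seed_specific", ]
cat("Seed-specific genes (tau > 0.6, peak in a seed stage):", nrow(ss), "\n")
cat("Median tau among seed-specific genes:",
    round(median(ss$tau), 3), "\n")

flags <- s3s5_higher_in_large(ds$de_table)
de_pass <- names(flags)[flags]
write.table(data.frame(gene_id = de_pass),
            "results/de_s3s5_higher_in_large.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Genes higher in the large-seeded cultivar at S3 and/or S5:",
    length(de_pass), "\n")
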