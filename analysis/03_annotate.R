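#!/usr/bin/env Rscript
# Annotate the differentiating variants: genomic region (promoter = 2 kb
# upstream of the TSS, strand-aware), coding consequence (synonymous,
# non-synonymous, large-effect: frameshift/start-loss/stop-gain/splice-site),
# Ts/Tv spectrum, InDel length spectrum, per-100-kb window densities and
# highly polymorphic gene outliers (above the third quartile of per-kb
# density).

suppressMessages(library(seedvar))

ds <- read_dataset("results/dataset")
diff <- read.table("results/differentiating_variants.tsv", sep = "\t",
                   header = TRUE)
ann <- annotate_variants(diff, ds$genes, ds$genome)
write.table(ann, "results/annotated_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Regions:\n"); print(table(ann$region))
cat("Consequences (genic variants):\n")
print(table(ann$consequence[!is.na(ann$gene_id)]))

snps <- ann[ann$class == "SNP", ]
tt <- ts_tv(snps$ref, snps$alt)
cat(sprintf("Transitions: %d (%.1f%%), transversions: %d (%.1f%%)\n",
            tt$transitions, 100 * tt$transitions / nrow(snps),
            tt$transversions, 100 * tt$transversions / nrow(snps)))

ind <- ann[ann$class == "InDel", ]
sp <- indel_spectrum(ind$ref, ind$alt)
write.table(sp, "results/indel_spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Insertions:", sum(sp$count[sp$type == "insertion"]),
    "; deletions:", sum(sp$count[sp$type == "deletion"]), "\n")

w <- window_frequency(ann, ds$genome)
write.table(w$windows, "results/window_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Per-chromosome frequency (per 100 kb):\n"); print(w$chromosomes)

gsum <- gene_variant_summary(ann, ds$genes)
write.table(gsum, "results/gene_variant_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (rg in c("exonic", "intronic")) {
  out <- polymorphic_gene_outliers(gsum, rg)
  cat(sprintf("Highly polymorphic genes (%s, density > Q3 = %.3f): %d\n",
              rg, out$q3, length(out$genes)))
}
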