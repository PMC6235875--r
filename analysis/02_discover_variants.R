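#!/usr/bin/env Rscript
# Discover DNA polymorphisms that differentiate the small- and large-seeded
# cultivar pairs: per-cultivar calls are filtered at read depth >= 10 and
# alternate fraction >= 0.9, clustered variants (3+ within any 10-bp window)
# are removed, and sites where both small cultivars agree, both large
# cultivars agree, and the groups differ are retained.

suppressMessages(library(seedvar))

ds <- read_dataset("results/dataset")
groups <- cultivar_groups()
diff <- group_differential(ds$calls, ds$coverage, groups$small, groups$large)
write.table(diff, "results/differentiating_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Calls read:", nrow(ds$calls), "; passing site filters:",
    nrow(filter_calls(ds$calls)), "\n")
cat("Group-differentiating variants:", nrow(diff), "\n")
print(table(diff$class))

# one-to-one comparisons mirror the group set
for (a in groups$small) {
  for (b in groups$large) {
    pw <- pairwise_differential(ds$calls, ds$coverage, a, b)
    cat(sprintf("  %s vs %s: %d differential sites\n", a, b, nrow(pw)))
  }
}
cat("Wrote results/differentiating_variants.tsv\n")
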