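comp1 <- function(b) chartr("ACGT", "TGCA", b)

test_that("region assignment is strand-aware with exon>intron>promoter", {
  genome <- c(chr1 = strrep("A", 60000))
  gplus <- list(gene_id = "gP", tx_id = "gP.1", chrom = "chr1", strand = "+",
                start = 5000L, end = 7000L,
                exons = data.frame(start = c(5000L, 6000L),
                                   end = c(5500L, 7000L)),
                cds = data.frame(start = c(5100L, 6000L),
                                 end = c(5500L, 6900L), phase = c(0L, 2L)))
  gminus <- list(gene_id = "gM", tx_id = "gM.1", chrom = "chr1",
                 strand = "-", start = 10000L, end = 12000L,
                 exons = data.frame(start = 10000L, end = 12000L),
                 cds = data.frame(start = 10100L, end = 11900L, phase = 0L))
  genes <- list(gplus, gminus)
  v <- data.frame(chrom = "chr1",
                  pos = c(3499L,   # 1501 bp upstream of the + TSS at 5000
                          12499L,  # 500 bp upstream of the - TSS at 11999
                          39999L,  # far from any gene
                          5200L,   # inside exon 1 of gP
                          5700L,   # intron of gP
                          4999L),  # 1 bp upstream of gP
                  ref = "A")
  out <- assign_region(v, genes)
  expect_identical(out$region,
                   c("promoter", "promoter", "intergenic", "exon", "intron",
                     "promoter"))
  expect_identical(out$gene_id[c(1, 2, 4, 5)], c("gP", "gM", "gP", "gP"))
  # beyond 2 kb upstream: intergenic
  v2 <- data.frame(chrom = "chr1", pos = 2999L, ref = "A")
  expect_identical(assign_region(v2, genes)$region, "intergenic")
})

test_that("coding consequences follow the genetic code on both strands", {
  for (strand in c("+", "-")) {
    toy <- toy_gene(strand)
    g <- toy$gene; genome <- toy$genome
    gp <- cds_positions(g)
    at <- function(p, len = 1) substr(genome[["chrT"]], p + 1, p + len)
    # transcript base b substituted at transcript index ti
    sub_at <- function(ti, b) {
      p <- gp[ti]
      list(pos = p, ref = at(p), alt = if (strand == "+") b else comp1(b))
    }
    cc <- function(v) call_consequence("chrT", v$pos, v$ref, v$alt, g, genome)

    # codon2 GAA -> GAG (Glu -> Glu)
    expect_identical(cc(sub_at(6L, "G"))$consequence, "synonymous")
    # codon3 TGG -> TGA
    res <- cc(sub_at(9L, "A"))
    expect_identical(res$consequence, "large_effect")
    expect_identical(res$subtype, "stop_gain")
    # codon2 GAA -> CAA (Glu -> Gln)
    expect_identical(cc(sub_at(4L, "C"))$consequence, "non_synonymous")
    # any hit to the initiator ATG
    res <- cc(sub_at(2L, "A"))
    expect_identical(res$subtype, "start_loss")
    # native stop TAA -> TGA: protein unchanged
    expect_identical(cc(sub_at(17L, "G"))$consequence, "synonymous")

    # 2-bp deletion inside the CDS -> frameshift
    p6 <- sort(gp[4:6])   # codon 2, forward-contiguous
    anchor <- p6[1]
    v <- list(pos = anchor, ref = at(anchor, 3), alt = at(anchor, 1))
    res <- cc(v)
    expect_identical(res$subtype, "frameshift")

    # 3-bp in-frame deletion of codon 5 (CTG) -> non-synonymous
    p5 <- sort(gp[13:15])
    anchor <- p5[1] - 1L
    v <- list(pos = anchor, ref = at(anchor, 4), alt = at(anchor, 1))
    expect_identical(cc(v)$consequence, "non_synonymous")

    # splice donor/acceptor SNPs
    intr <- data.frame(start = g$exons$end[1], end = g$exons$start[2])
    for (p in c(intr$start, intr$start + 1L, intr$end - 2L, intr$end - 1L)) {
      v <- list(pos = p, ref = at(p), alt = setdiff(c("A", "C", "G", "T"),
                                                    at(p))[1])
      expect_identical(cc(v)$subtype, "splice_site")
    }
    # intron interior SNP -> non_coding
    p <- intr$start + 10L
    v <- list(pos = p, ref = at(p), alt = setdiff(c("A", "C", "G", "T"),
                                                  at(p))[1])
    expect_identical(cc(v)$consequence, "non_coding")
    # UTR SNP -> non_coding
    putr <- if (strand == "+") g$start + 1L else g$end - 2L
    v <- list(pos = putr, ref = at(putr), alt = comp1(at(putr)))
    expect_identical(cc(v)$consequence, "non_coding")

    # in-frame 3-bp insertion at a codon boundary -> non-synonymous
    p <- gp[6]   # last base of codon 2
    if (strand == "+") {
      v <- list(pos = p, ref = at(p), alt = paste0(at(p), "AAA"))
    } else {
      v <- list(pos = p - 1L, ref = at(p - 1L),
                alt = paste0(at(p - 1L), "TTT"))
    }
    expect_identical(cc(v)$consequence, "non_synonymous")

    expect_error(call_consequence("chrT", 5L, "A", "G", g, genome),
                 "contract error")
  }
})

test_that("call_consequence matches the genome-editing oracle", {
  cfg <- synth_config(seed = 21, n_chroms = 1, chrom_length = 100000,
                      n_genes = 10, n_diff_variants = c(SNP = 0),
                      n_confound_variants = 0, n_seed_specific = 0,
                      n_qtls = 0, n_density_clusters = 0)
  gm <- generate_gene_models(cfg, generate_reference(cfg))
  set.seed(99)
  n_checked <- 0
  while (n_checked < 300) {
    g <- gm$genes[[sample(length(gm$genes), 1)]]
    v <- random_gene_variant(g, gm$genome)
    if (is.null(v) || v$ref == v$alt) next
    got <- call_consequence(g$chrom, v$pos, v$ref, v$alt, g, gm$genome)
    want <- oracle_consequence(g$chrom, v$pos, v$ref, v$alt, g, gm$genome)
    expect_identical(got$consequence, want$consequence,
                     label = sprintf("%s:%d %s>%s (%s)", g$gene_id, v$pos,
                                     v$ref, v$alt, g$strand))
    expect_identical(got$subtype, want$subtype)
    n_checked <- n_checked + 1
  }
})

test_that("consequences are invariant under genome reverse-complementation", {
  ds <- small_ds()
  res <- small_run()
  L <- nchar(ds$genome)
  flipped_genome <- setNames(vapply(ds$genome, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1)), names(ds$genome))
  flip_gene <- function(g) {
    n <- L[[g$chrom]]
    fl <- function(s, e) data.frame(start = n - e, end = n - s)
    ex <- fl(g$exons$start, g$exons$end)
    cd <- fl(g$cds$start, g$cds$end)
    list(gene_id = g$gene_id, tx_id = g$tx_id, chrom = g$chrom,
         strand = if (g$strand == "+") "-" else "+",
         start = n - g$end, end = n - g$start,
         exons = ex[order(ex$start), ],
         cds = cbind(cd[order(cd$start), ], phase = 0L))
  }
  flipped_genes <- lapply(ds$genes, flip_gene)
  gid <- vapply(ds$genes, `[[`, character(1), "gene_id")
  snps <- res$annotated[res$annotated$class == "SNP" &
                          res$annotated$region %in% c("exon", "intron"), ]
  for (i in seq_len(nrow(snps))) {
    g2 <- flipped_genes[[match(snps$gene_id[i], gid)]]
    p2 <- L[[snps$chrom[i]]] - 1L - snps$pos[i]
    got <- call_consequence(snps$chrom[i], p2, comp1(snps$ref[i]),
                            comp1(snps$alt[i]), g2, flipped_genome)
    expect_identical(got$consequence, snps$consequence[i])
  }
})

test_that("Ts/Tv and InDel spectra conserve their inputs", {
  expect_equal(ts_tv("A", "G")$transitions, 1)
  expect_equal(ts_tv("C", "T")$transitions, 1)
  expect_equal(ts_tv("A", "T")$transversions, 1)
  expect_error(ts_tv("AT", "GC"), "SNP")
  set.seed(7)
  ref <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  alt <- vapply(ref, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  r <- ts_tv(ref, alt)
  expect_equal(r$transitions + r$transversions, 100)

  expect_equal(indel_spectrum("A", "ATG"),
               data.frame(type = "insertion", length = 2L, count = 1L))
  expect_equal(indel_spectrum("ATTA", "A"),
               data.frame(type = "deletion", length = 3L, count = 1L))
  sp <- indel_spectrum(c("A", "AT", "ATTA"), c("AG", "A", "A"))
  expect_equal(sum(sp$count), 3)
  expect_error(indel_spectrum("AT", "GC"), "zero length")
})

test_that("window frequencies tile the chromosome and conserve counts", {
  genome <- c(chr1 = strrep("A", 1000000), chr2 = strrep("A", 250000))
  set.seed(5)
  v <- data.frame(chrom = "chr1",
                  pos = sort(sample.int(1000000, 142) - 1L),
                  class = "SNP")
  w <- window_frequency(v, genome)
  expect_equal(w$chromosomes$frequency[w$chromosomes$chrom == "chr1"], 14.2)
  expect_equal(sum(w$windows$count[w$windows$chrom == "chr1"]), 142)
  expect_true(all(w$windows$count[w$windows$chrom == "chr2"] == 0))
  # last partial tile is normalized by its true length
  genome2 <- c(chr1 = strrep("A", 150000))
  v2 <- data.frame(chrom = "chr1", pos = c(10L, 120000L))
  w2 <- window_frequency(v2, genome2)
  expect_equal(w2$windows$end[2] - w2$windows$start[2], 50000)
  expect_equal(w2$windows$frequency[2], 1 / 50000 * 100000)
})

test_that("third-quartile outliers match the interpolated quantile", {
  summ <- data.frame(gene_id = paste0("g", 1:5),
                     exonic_density = c(1, 2, 3, 4, 100),
                     intronic_density = rep(2, 5))
  out <- polymorphic_gene_outliers(summ, "exonic")
  expect_equal(out$q3, 4)
  expect_identical(out$genes, "g5")
  expect_identical(polymorphic_gene_outliers(summ, "intronic")$genes,
                   character(0))
  expect_error(polymorphic_gene_outliers(summ[1:3, ], "exonic"),
               "insufficient data")
  set.seed(17)
  for (i in 1:100) {
    d <- round(rexp(sample(4:50, 1)), 3) + 0.001
    s <- data.frame(gene_id = paste0("g", seq_along(d)), exonic_density = d,
                    intronic_density = d)
    got <- polymorphic_gene_outliers(s, "exonic")
    expect_equal(got$q3, oracle_q3(d))
    expect_setequal(got$genes, s$gene_id[d > oracle_q3(d)])
  }
})

test_that("planted region and effect labels are recovered exactly", {
  ds <- small_ds()
  res <- small_run()
  kept <- ds$truth$variants[ds$truth$variants$expect == "kept", ]
  m <- merge(kept, res$annotated, by = c("chrom", "pos"))
  expect_equal(nrow(m), nrow(kept))
  expect_identical(m$region.x, m$region.y)
  expect_identical(m$effect, m$consequence)
  has_sub <- !is.na(m$subtype.x)
  expect_identical(m$subtype.x[has_sub], m$subtype.y[has_sub])
  # region partition: every variant gets exactly one region, counts sum
  expect_equal(sum(table(res$annotated$region)), nrow(res$diff))
})
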