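test_that("reference generation is deterministic and validates its config", {
  cfg <- synth_config(seed = 7, n_chroms = 2, chrom_length = 100000,
                      n_genes = 0, n_diff_variants = c(SNP = 0),
                      n_confound_variants = 0, n_seed_specific = 0,
                      n_qtls = 0, n_density_clusters = 0)
  g1 <- generate_reference(cfg)
  g2 <- generate_reference(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), c(chr1 = 100000L, chr2 = 100000L))
  expect_true(all(grepl("^[ACGT]+$", g1)))
  # uniform base model: GC fraction within a binomial band around 0.5
  gc <- sum(strsplit(g1[["chr1"]], "")[[1]] %in% c("G", "C")) / 100000
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)

  expect_error(synth_config(chrom_length = 0), "invalid config")
  expect_error(synth_config(n_genes = -1), "invalid config")
  expect_error(synth_config(n_diff_variants = c(foo = 5)), "invalid config")
})

test_that("gene models have valid CDS, splice sites and strand handling", {
  ds <- small_ds()
  for (g in ds$genes) {
    cds <- gene_cds_seq(g, ds$genome)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_equal(nchar(cds) %% 3, 0)
    aa <- strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(cds))), "")[[1]]
    expect_identical(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
    ex <- g$exons[order(g$exons$start), ]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end[-nrow(ex)] < ex$start[-1]))
    intr <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
    for (i in seq_len(nrow(intr))) {
      expect_gte(intr$end[i] - intr$start[i], 20)
      donor_acceptor <- substr(ds$genome[[g$chrom]], intr$start[i] + 1,
                               intr$start[i] + 2)
      acceptor <- substr(ds$genome[[g$chrom]], intr$end[i] - 1, intr$end[i])
      if (g$strand == "+") {
        expect_identical(donor_acceptor, "GT")
        expect_identical(acceptor, "AG")
      } else {
        # transcript-sense GT..AG appears as CT..AC on the forward strand
        expect_identical(donor_acceptor, "CT")
        expect_identical(acceptor, "AC")
      }
    }
  }
  # a minus-strand gene starts its CDS at the highest-coordinate CDS edge
  minus <- Filter(function(g) g$strand == "-", ds$genes)[[1]]
  gp <- cds_positions(minus)
  expect_identical(gp[1], max(minus$cds$end) - 1L)
  first_codon <- paste(vapply(gp[1:3], function(p) {
    chartr("ACGT", "TGCA", substr(ds$genome[[minus$chrom]], p + 1, p + 1))
  }, character(1)), collapse = "")
  expect_identical(first_codon, "ATG")
})

test_that("gene placement fails cleanly when the genome is too small", {
  cfg <- synth_config(seed = 1, n_chroms = 1, chrom_length = 20000,
                      n_genes = 50, n_diff_variants = c(SNP = 0),
                      n_confound_variants = 0, n_seed_specific = 0,
                      n_qtls = 0, n_density_clusters = 0)
  expect_error(generate_gene_models(cfg, generate_reference(cfg)),
               "placement error")
})

test_that("the whole dataset is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 3)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted variants honour their construction rules", {
  ds <- small_ds()
  tv <- ds$truth$variants
  groups <- cultivar_groups()

  # density clusters: three SNPs spanning at most 9 bp
  cl <- tv[tv$expect == "density_removed", ]
  expect_equal(nrow(cl) %% 3, 0)
  spans <- tapply(cl$pos, cumsum(seq_len(nrow(cl)) %% 3 == 1),
                  function(p) max(p) - min(p))
  expect_true(all(spans <= 9))

  # within-group polymorphic confounders differ inside one group
  wg <- tv[tv$expect == "not_differentiating" &
             tv$small_allele == tv$ref & tv$large_allele == tv$ref, ]
  per_cult <- as.matrix(wg[, paste0("allele_", c(groups$small,
                                                 groups$large))])
  expect_true(all(rowSums(per_cult != wg$ref) == 1))

  # every planted site with a non-reference carrier appears in >= 1 VCF
  al <- as.matrix(tv[, paste0("allele_", c(groups$small, groups$large))])
  has_carrier <- vapply(seq_len(nrow(tv)), function(i) {
    any(al[i, ] != tv$ref[i])
  }, logical(1))
  key_calls <- paste(ds$calls$chrom, ds$calls$pos)
  expect_true(all(paste(tv$chrom, tv$pos)[has_carrier] %in% key_calls))

  # planted stop-gains substitute a codon into TAA/TAG/TGA
  gid <- vapply(ds$genes, `[[`, character(1), "gene_id")
  sg <- tv[!is.na(tv$subtype) & tv$subtype == "stop_gain", ]
  for (i in seq_len(nrow(sg))) {
    g <- ds$genes[[match(sg$gene_id[i], gid)]]
    cc <- call_consequence(sg$chrom[i], sg$pos[i], sg$ref[i],
                           sg$large_allele[i], g, ds$genome)
    expect_identical(cc$subtype, "stop_gain")
  }
})

test_that("planted expression profiles meet their targets", {
  ds <- small_ds()
  meta <- ds$tissue_meta
  for (g in ds$truth$seed_specific_genes) {
    ti <- tau_index(ds$expression[g, ])
    expect_gt(ti$tau, 0.6)
    expect_true(meta$is_seed[ti$peak])
  }
  # planted DE candidates pass the gate at S3 and/or S5, higher in large
  de <- ds$de_table
  flags <- s3s5_higher_in_large(de)
  expect_true(all(ds$truth$candidate_genes %in% names(flags)[flags]))
})

test_that("zero QTLs still yields a runnable pipeline", {
  cfg <- synth_config(seed = 5, n_chroms = 1, chrom_length = 150000,
                      n_genes = 10,
                      n_diff_variants = c(SNP = 30, MNP = 5, InDel = 10,
                                          complex = 5),
                      n_confound_variants = 5, n_seed_specific = 3,
                      n_qtls = 0, n_density_clusters = 1)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$qtls), 0)
  res <- run_pipeline(ds)
  expect_true(all(is.na(res$candidates$candidates$qtl_member)) ||
                all(!res$candidates$candidates$qtl_member))
})
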