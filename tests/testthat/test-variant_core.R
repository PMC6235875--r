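test_that("variant classes follow the four-way definition", {
  expect_identical(classify_variant("A", "G"), "SNP")
  expect_identical(classify_variant("AT", "GC"), "MNP")
  expect_identical(classify_variant("A", "ATG"), "InDel")
  expect_identical(classify_variant("ATTA", "A"), "InDel")
  expect_identical(classify_variant("ATG", "GC"), "complex")
  # untrimmed representations reduce to their minimal class
  expect_identical(classify_variant("ATT", "ATA"), "SNP")
  expect_identical(classify_variant("CATTA", "CA"), "InDel")
  expect_error(classify_variant("A", "A"), "identical")
})

test_that("depth and alternate-fraction filters match the printed thresholds", {
  calls <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                      cultivar = "JGK3",
                      depth = c(12, 9, 10, 40),
                      alt_fraction = c(0.95, 1.0, 0.90, 0.89))
  kept <- filter_calls(calls)
  expect_equal(kept$pos, c(1, 3))   # depth 9 fails, 10 passes; AF .89 fails
  expect_equal(nrow(filter_calls(calls[0, ])), 0)
  expect_error(filter_calls(calls, min_depth = 0), "positive")
})

test_that("the 10-bp density rule removes clustered variants", {
  expect_identical(density_filter(c(100L, 105L, 109L)), integer(0))
  expect_identical(density_filter(c(100L, 105L, 120L)),
                   c(100L, 105L, 120L))
  expect_identical(density_filter(c(100L, 109L, 110L)),
                   c(100L, 109L, 110L))
  expect_error(density_filter(c(5L, 1L)), "sorted")
})

test_that("density filter agrees with the exhaustive window scan", {
  set.seed(401)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    p <- sort(sample.int(300, n))
    expect_identical(density_filter(p),
                     p[!oracle_density_removed(p)],
                     label = paste("positions", paste(p, collapse = ",")))
  }
})

make_site <- function(alleles, depths = rep(30, 4), afs = rep(0.97, 4),
                      cov_depths = rep(30, 4)) {
  groups <- cultivar_groups()
  cult <- c(groups$small, groups$large)
  rows <- list(); cov <- list()
  for (i in seq_along(cult)) {
    if (alleles[i] != "A") {   # "A" is the reference in these fixtures
      rows[[length(rows) + 1]] <- data.frame(
        chrom = "chr1", pos = 100L, ref = "A", alt = alleles[i],
        cultivar = cult[i], depth = depths[i], alt_fraction = afs[i])
    }
    cov[[length(cov) + 1]] <- data.frame(chrom = "chr1", pos = 100L,
                                         cultivar = cult[i],
                                         depth = cov_depths[i])
  }
  list(calls = do.call(rbind, rows) %||%
         data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    cultivar = character(0), depth = numeric(0),
                    alt_fraction = numeric(0)),
       coverage = do.call(rbind, cov))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("group differential requires confident, group-consistent calls", {
  groups <- cultivar_groups()
  # small=(A,A) reference, large=(G,G): emitted
  s <- make_site(c("A", "A", "G", "G"))
  out <- group_differential(s$calls, s$coverage, groups$small, groups$large)
  expect_equal(nrow(out), 1)
  expect_identical(out$small_allele, "A")
  expect_identical(out$large_allele, "G")
  expect_identical(out$class, "SNP")

  # within-group polymorphism: not emitted
  s <- make_site(c("A", "G", "G", "G"))
  expect_equal(nrow(group_differential(s$calls, s$coverage, groups$small,
                                       groups$large)), 0)

  # one large cultivar's call at depth 7: not emitted
  s <- make_site(c("A", "A", "G", "G"), depths = c(30, 30, 30, 7))
  expect_equal(nrow(group_differential(s$calls, s$coverage, groups$small,
                                       groups$large)), 0)

  # a reference cultivar covered at depth 7: not emitted
  s <- make_site(c("A", "A", "G", "G"), cov_depths = c(30, 7, 30, 30))
  expect_equal(nrow(group_differential(s$calls, s$coverage, groups$small,
                                       groups$large)), 0)

  # two different non-reference alleles still differentiate the groups
  s <- make_site(c("T", "T", "G", "G"))
  out <- group_differential(s$calls, s$coverage, groups$small, groups$large)
  expect_equal(nrow(out), 1)
  expect_identical(out$alt, "G")   # the large-group allele is substituted

  # unknown cultivar id
  bad <- make_site(c("A", "A", "G", "G"))
  bad$calls$cultivar[1] <- "Mystery"
  expect_error(group_differential(bad$calls, bad$coverage, groups$small,
                                  groups$large), "unknown cultivar")
})

test_that("swapping the group labels preserves sites and swaps alleles", {
  ds <- small_ds()
  groups <- cultivar_groups()
  fwd <- group_differential(ds$calls, ds$coverage, groups$small,
                            groups$large)
  rev <- group_differential(ds$calls, ds$coverage, groups$large,
                            groups$small)
  expect_identical(paste(fwd$chrom, fwd$pos), paste(rev$chrom, rev$pos))
  expect_identical(fwd$small_allele, rev$large_allele)
  expect_identical(fwd$large_allele, rev$small_allele)
})

test_that("group set is contained in every small-vs-large pairwise set", {
  ds <- small_ds()
  groups <- cultivar_groups()
  grp <- group_differential(ds$calls, ds$coverage, groups$small,
                            groups$large)
  gkey <- paste(grp$chrom, grp$pos)
  for (a in groups$small) {
    for (b in groups$large) {
      pw <- pairwise_differential(ds$calls, ds$coverage, a, b)
      expect_true(all(gkey %in% paste(pw$chrom, pw$pos)),
                  label = paste(a, "vs", b))
    }
  }
  expect_error(pairwise_differential(ds$calls, ds$coverage, "JGK3", "JGK3"),
               "must differ")
})

test_that("planted differentiating set is recovered exactly", {
  ds <- small_ds()
  res <- small_run()
  kept <- ds$truth$variants[ds$truth$variants$expect == "kept", ]
  expect_setequal(paste(res$diff$chrom, res$diff$pos),
                  paste(kept$chrom, kept$pos))
  m <- merge(kept, res$diff, by = c("chrom", "pos"))
  expect_equal(nrow(m), nrow(kept))
  expect_identical(m$class.x, m$class.y)
  expect_identical(m$small_allele.x, m$small_allele.y)
  expect_identical(m$large_allele.x, m$large_allele.y)
})
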