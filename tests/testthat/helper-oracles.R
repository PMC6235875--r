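# Independent oracles and shared fixtures, built in code.

# ---- brute-force density scan: slide every possible 10-bp window ----------
oracle_density_removed <- function(positions, window_bp = 10L,
                                   max_in_window = 2L) {
  removed <- logical(length(positions))
  if (!length(positions)) return(removed)
  for (w in (min(positions) - window_bp + 1L):max(positions)) {
    inside <- positions >= w & positions <= w + window_bp - 1L
    if (sum(inside) > max_in_window) removed[inside] <- TRUE
  }
  removed
}

# ---- brute-force consequence oracle: edit the genome, shift coordinates,
# re-extract and re-translate the CDS --------------------------------------
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_translate <- function(s) {
  n <- (nchar(s) %/% 3L) * 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                     if.fuzzy.codon = "X"))
}

oracle_introns <- function(gene) {
  ex <- gene$exons[order(gene$exons$start), ]
  n <- nrow(ex)
  if (n < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n], end = ex$start[-1])
}

oracle_consequence <- function(chrom, pos, ref, alt, gene, genome,
                               splice_window_bp = 2L) {
  s <- pos
  e <- pos + nchar(ref)
  intr <- oracle_introns(gene)
  for (i in seq_len(nrow(intr))) {
    if ((s < intr$start[i] + splice_window_bp && e > intr$start[i]) ||
        (s < intr$end[i] && e > intr$end[i] - splice_window_bp)) {
      return(list(consequence = "large_effect", subtype = "splice_site"))
    }
  }
  gseq <- genome[[chrom]]
  new_seq <- paste0(substr(gseq, 1, pos), alt,
                    substr(gseq, pos + nchar(ref) + 1, nchar(gseq)))
  delta <- nchar(alt) - nchar(ref)
  shift <- function(x) ifelse(x >= e, x + delta, x)
  extract <- function(seq, segs) {
    segs <- segs[order(segs$start), ]
    out <- paste(substring(seq, segs$start + 1, segs$end), collapse = "")
    if (gene$strand == "-") oracle_revcomp(out) else out
  }
  ref_cds <- extract(gseq, gene$cds)
  alt_cds <- extract(new_seq, data.frame(start = shift(gene$cds$start),
                                         end = shift(gene$cds$end)))
  if (identical(ref_cds, alt_cds)) {
    return(list(consequence = "non_coding", subtype = NA_character_))
  }
  if (substr(alt_cds, 1, 3) != "ATG") {
    return(list(consequence = "large_effect", subtype = "start_loss"))
  }
  if ((nchar(alt_cds) - nchar(ref_cds)) %% 3L != 0L) {
    return(list(consequence = "large_effect", subtype = "frameshift"))
  }
  aa <- oracle_translate(alt_cds)
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0 && star < nchar(aa)) {
    return(list(consequence = "large_effect", subtype = "stop_gain"))
  }
  strip <- function(p) sub("\\*.*$", "", p)
  if (strip(aa) == strip(oracle_translate(ref_cds))) {
    list(consequence = "synonymous", subtype = NA_character_)
  } else {
    list(consequence = "non_synonymous", subtype = NA_character_)
  }
}

# random variants confined to single gene features, so both routes are
# well-defined; covers CDS SNPs/MNPs/indels, splice sites, start codon,
# UTRs and intron interiors
random_gene_variant <- function(gene, genome) {
  kind <- sample(c("cds_snp", "cds_mnp", "cds_del", "cds_ins", "splice",
                   "start", "utr_snp", "intron_snp"), 1,
                 prob = c(0.3, 0.1, 0.15, 0.15, 0.1, 0.05, 0.05, 0.1))
  chrom <- gene$chrom
  bases <- c("A", "C", "G", "T")
  other <- function(b) sample(setdiff(bases, b), 1)
  at <- function(p, len = 1) substr(genome[[chrom]], p + 1, p + len)
  segs <- gene$cds[order(gene$cds$start), ]
  segs <- segs[segs$end - segs$start >= 12, , drop = FALSE]
  pick_cds_pos <- function(margin, len) {
    i <- sample(nrow(segs), 1)
    sample((segs$start[i] + margin):(segs$end[i] - margin - len), 1)
  }
  if (kind %in% c("cds_snp", "utr_snp", "intron_snp", "splice", "start")) {
    p <- switch(kind,
      cds_snp = pick_cds_pos(1L, 1L),
      start = {
        gp <- cds_positions(gene)
        sample(gp[1:3], 1)
      },
      splice = {
        intr <- oracle_introns(gene)
        i <- sample(nrow(intr), 1)
        sample(c(intr$start[i], intr$start[i] + 1L, intr$end[i] - 2L,
                 intr$end[i] - 1L), 1)
      },
      intron_snp = {
        intr <- oracle_introns(gene)
        i <- sample(nrow(intr), 1)
        sample((intr$start[i] + 4L):(intr$end[i] - 5L), 1)
      },
      utr_snp = {
        ex <- gene$exons[order(gene$exons$start), ]
        cd <- gene$cds[order(gene$cds$start), ]
        # 5'-most or 3'-most exon fringe outside the CDS
        if (gene$strand == "+" || runif(1) < 0.5) {
          lo <- ex$start[1]; hi <- min(cd$start)
        } else {
          lo <- max(cd$end); hi <- ex$end[nrow(ex)]
        }
        if (hi - lo < 4) return(NULL)
        sample((lo + 1L):(hi - 2L), 1)
      })
    if (is.null(p)) return(NULL)
    ref <- at(p)
    return(list(pos = p, ref = ref, alt = other(ref)))
  }
  if (kind == "cds_mnp") {
    p <- pick_cds_pos(2L, 3L)
    ref <- at(p, 3)
    rb <- strsplit(ref, "")[[1]]
    ab <- c(other(rb[1]), sample(bases, 1), other(rb[3]))
    return(list(pos = p, ref = ref, alt = paste(ab, collapse = "")))
  }
  if (kind == "cds_del") {
    d <- sample(1:4, 1)
    p <- pick_cds_pos(2L, d + 1L)
    ref <- at(p, d + 1)
    return(list(pos = p, ref = ref, alt = substr(ref, 1, 1)))
  }
  # cds_ins
  d <- sample(1:4, 1)
  p <- pick_cds_pos(2L, 2L)
  ref <- at(p)
  list(pos = p, ref = ref,
       alt = paste0(ref, paste(sample(bases, d, replace = TRUE),
                               collapse = "")))
}

# ---- quartile / containment oracles ---------------------------------------
oracle_q3 <- function(x) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h)
  if (lo == h) x[lo] else x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_contained <- function(gs, ge, gchrom, qtls) {
  hits <- character(0)
  for (i in seq_len(nrow(qtls))) {
    if (qtls$chrom[i] == gchrom && qtls$start[i] <= gs &&
        qtls$end[i] >= ge) {
      hits <- c(hits, qtls$name[i])
    }
  }
  hits
}

# ---- shared fixtures -------------------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 11) {
  synth_config(seed = seed, n_chroms = 1, chrom_length = 300000, n_genes = 25,
               n_diff_variants = c(SNP = 120, MNP = 20, InDel = 40,
                                   complex = 20),
               n_confound_variants = 30, n_seed_specific = 8, n_qtls = 3,
               n_density_clusters = 3)
}

small_ds <- function() {
  if (is.null(.fixture_cache$ds)) {
    .fixture_cache$ds <- simulate_dataset(small_cfg())
  }
  .fixture_cache$ds
}

small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_pipeline(small_ds())
  }
  .fixture_cache$run
}

# a handcrafted plus-strand two-exon gene with known codons:
# CDS = ATG GAA TGG AAA CTG TAA, intron between codons 3 and 4
toy_gene <- function(strand = "+") {
  utr5 <- "TTTTT"; utr3 <- "GGGGG"
  ex1_cds <- "ATGGAATGG"
  intron <- paste0("GT", strrep("C", 20), "AG")
  ex2_cds <- "AAACTGTAA"
  sense <- paste0(utr5, ex1_cds, intron, ex2_cds, utr3)
  L <- nchar(sense)
  off <- 100L
  pad <- function(n) strrep("A", n)
  if (strand == "+") {
    seq <- paste0(pad(off), sense, pad(100))
    exons <- data.frame(start = off + c(0L, 38L), end = off + c(14L, 52L))
    cds <- data.frame(start = off + c(5L, 38L), end = off + c(14L, 47L),
                      phase = c(0L, 0L))
  } else {
    seq <- paste0(pad(off), oracle_revcomp(sense), pad(100))
    flip <- function(s, e) list(start = off + L - e, end = off + L - s)
    ex <- flip(c(0L, 38L), c(14L, 52L))
    cd <- flip(c(5L, 38L), c(14L, 47L))
    exons <- data.frame(start = rev(ex$start), end = rev(ex$end))
    cds <- data.frame(start = rev(cd$start), end = rev(cd$end),
                      phase = c(0L, 0L))
  }
  genome <- c(chrT = seq)
  gene <- list(gene_id = "toy", tx_id = "toy.1", chrom = "chrT",
               strand = strand, start = off, end = off + L,
               exons = exons, cds = cds)
  stopifnot(gene_cds_seq(gene, genome) == "ATGGAATGGAAACTGTAA")
  list(gene = gene, genome = genome, off = off, L = L)
}
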