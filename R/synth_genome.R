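#' Generate a random reference genome
#'
#' Uniform-base random chromosomes. Deterministic under a fixed config seed.
#'
#' @param cfg a [synth_config()].
#' @return named character vector of uppercase A/C/G/T sequences
#'   (`chr1`, `chr2`, ...).
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    paste(sample(BASES, cfg$chrom_length, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(cfg$n_chroms))
  seqs
}

#' Generate gene models and write their sequences into the genome
#'
#' Places non-overlapping multi-exon genes on both strands, each with a valid
#' CDS (ATG start, single stop at the end, length divisible by 3, no internal
#' stop codon) and canonical GT..AG introns. Gene loci are overwritten in the
#' returned genome so that every model is consistent with the emitted
#' sequence. At least 2 kb is kept clear upstream of every transcription
#' start so promoter labels are unambiguous.
#'
#' @param cfg a [synth_config()].
#' @param genome named character vector from [generate_reference()].
#' @return list with `genes` (list of gene models; see Details) and `genome`
#'   (the updated sequences).
#' @details A gene model is a list with `gene_id`, `tx_id`, `chrom`, `strand`,
#'   `start`/`end` (0-based half-open span), `exons` (data.frame of sorted
#'   0-based half-open intervals) and `cds` (data.frame with `start`, `end`,
#'   `phase`).
#' @export
generate_gene_models <- function(cfg, genome) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  n_per <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1L)))
  genes <- vector("list", cfg$n_genes)
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- names(genome)[ci]
    chars <- strsplit(genome[[chrom]], "")[[1]]
    chrom_len <- length(chars)
    cursor <- sample(2500:4000, 1L)
    for (k in seq_len(n_per[ci])) {
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      gb <- build_gene(strand)
      if (cursor + gb$len + 2500L > chrom_len) {
        stop("placement error: genome too small to place ", cfg$n_genes,
             " genes")
      }
      chars[(cursor + 1L):(cursor + gb$len)] <- gb$chars
      id <- sprintf("g%03d", gi)
      genes[[gi]] <- list(
        gene_id = id, tx_id = paste0(id, ".1"),
        chrom = chrom, strand = strand,
        start = cursor, end = cursor + gb$len,
        exons = data.frame(start = cursor + gb$exons$start,
                           end = cursor + gb$exons$end),
        cds = data.frame(start = cursor + gb$cds$start,
                         end = cursor + gb$cds$end,
                         phase = gb$cds$phase)
      )
      cursor <- cursor + gb$len + sample(4500:6500, 1L)
    }
    genome[[chrom]] <- paste(chars, collapse = "")
  }
  list(genes = genes, genome = genome)
}

# Construct one gene in transcript-sense coordinates, then orient it onto the
# forward strand. Returns forward-strand characters, length, and local
# 0-based half-open exon/CDS intervals (sorted by coordinate) with GFF3 phase.
build_gene <- function(strand) {
  k <- sample(2:4, 1L)
  n_cod <- sample(60:150, 1L)
  cds_len <- 3L * n_cod
  u5 <- sample(20:60, 1L)
  u3 <- sample(20:60, 1L)
  # split the CDS across k exons, every piece >= 30 bp
  repeat {
    cuts <- sort(sample(30:(cds_len - 30L), k - 1L))
    parts <- diff(c(0L, cuts, cds_len))
    if (all(parts >= 30L)) break
  }
  intron_len <- sample(150:400, k - 1L, replace = TRUE)
  exon_len <- parts
  exon_len[1L] <- exon_len[1L] + u5
  exon_len[k] <- exon_len[k] + u3

  cds_seq <- paste0("ATG",
                    paste(sample(nonstop_codons(), n_cod - 2L, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1L))
  stopifnot(!any(aa_vector(cds_seq)[-n_cod] == "*"))
  rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")
  tx_seq <- paste0(rand_seq(u5), cds_seq, rand_seq(u3))

  # sense-local layout: exon1 intron1 exon2 ... exonk
  pieces <- character(0)
  exon_s <- integer(k); exon_e <- integer(k)
  pos <- 0L
  tx_off <- 0L
  for (i in seq_len(k)) {
    exon_s[i] <- pos
    exon_e[i] <- pos + exon_len[i]
    pieces <- c(pieces, substr(tx_seq, tx_off + 1L, tx_off + exon_len[i]))
    tx_off <- tx_off + exon_len[i]
    pos <- pos + exon_len[i]
    if (i < k) {
      il <- intron_len[i]
      pieces <- c(pieces, paste0("GT", rand_seq(il - 4L), "AG"))
      pos <- pos + il
    }
  }
  gene_seq <- paste(pieces, collapse = "")
  L <- nchar(gene_seq)
  stopifnot(pos == L)

  # CDS segments in sense-local coordinates + phase in transcript order
  cds_lo <- u5
  cds_hi <- u5 + cds_len   # in transcript coordinates
  seg_s <- integer(0); seg_e <- integer(0); seg_phase <- integer(0)
  tx_pos <- 0L; done <- 0L
  for (i in seq_len(k)) {
    ex_tx_lo <- tx_pos
    ex_tx_hi <- tx_pos + exon_len[i]
    lo <- max(cds_lo, ex_tx_lo)
    hi <- min(cds_hi, ex_tx_hi)
    if (lo < hi) {
      seg_phase <- c(seg_phase, (3L - (done %% 3L)) %% 3L)
      # map transcript interval to sense-local genomic interval
      seg_s <- c(seg_s, exon_s[i] + (lo - ex_tx_lo))
      seg_e <- c(seg_e, exon_s[i] + (hi - ex_tx_lo))
      done <- done + (hi - lo)
    }
    tx_pos <- tx_pos + exon_len[i]
  }

  if (strand == "-") {
    gene_seq <- revcomp(gene_seq)
    flip <- function(s, e) list(start = L - e, end = L - s)
    ex <- flip(exon_s, exon_e)
    cd <- flip(seg_s, seg_e)
    o <- order(ex$start)
    exons <- data.frame(start = ex$start[o], end = ex$end[o])
    o2 <- order(cd$start)
    cds <- data.frame(start = cd$start[o2], end = cd$end[o2],
                      phase = seg_phase[o2])
  } else {
    exons <- data.frame(start = exon_s, end = exon_e)
    cds <- data.frame(start = seg_s, end = seg_e, phase = seg_phase)
  }
  list(chars = strsplit(gene_seq, "")[[1]], len = L, exons = exons, cds = cds)
}

#' Genomic positions of CDS bases in transcript order
#'
#' @param gene a gene model.
#' @return integer vector of 0-based genomic positions, 5' to 3' of the
#'   transcript (ascending for `+` genes, descending for `-` genes).
#' @export
cds_positions <- function(gene) {
  segs <- gene$cds[order(gene$cds$start), , drop = FALSE]
  if (gene$strand == "+") {
    unlist(Map(function(s, e) seq.int(s, e - 1L), segs$start, segs$end),
           use.names = FALSE)
  } else {
    unlist(rev(Map(function(s, e) seq.int(e - 1L, s), segs$start, segs$end)),
           use.names = FALSE)
  }
}

#' Spliced CDS sequence of a gene in transcript orientation
#'
#' @param gene a gene model.
#' @param genome named character vector of chromosome sequences.
#' @return the CDS string (starts ATG, ends with a stop codon for valid
#'   models).
#' @export
gene_cds_seq <- function(gene, genome) {
  segs <- gene$cds[order(gene$cds$start), , drop = FALSE]
  s <- paste(substring(genome[[gene$chrom]], segs$start + 1L, segs$end),
             collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

# introns as 0-based half-open intervals, sorted by coordinate
gene_introns <- function(gene) {
  ex <- gene$exons[order(gene$exons$start), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n], end = ex$start[-1L])
}
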