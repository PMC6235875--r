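# Planting of group-differentiating variants, confounders, density clusters
# and low-depth exclusions into the synthetic genome. Every planted record
# carries its construction-time region/effect label so downstream recovery can
# be checked by set equality.

# sample from a vector (never from 1:n when length(x) == 1)
resample <- function(x, n = 1L, ...) x[sample.int(length(x), n, ...)]

# largest-remainder allocation of n among named fractions
alloc_counts <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base) |> setNames(names(fracs))
}

.region_fracs <- list(
  SNP = c(intergenic = 0.517, promoter = 0.16, intron = 0.18, utr = 0.03,
          synonymous = 0.047, non_synonymous = 0.047, stop_gain = 0.008,
          start_loss = 0.005, splice_site = 0.006),
  MNP = c(intergenic = 0.56, promoter = 0.16, intron = 0.16,
          synonymous = 0.04, non_synonymous = 0.08),
  InDel = c(intergenic = 0.50, promoter = 0.17, intron = 0.17, utr = 0.03,
            frameshift = 0.07, inframe = 0.06),
  complex = c(intergenic = 0.66, promoter = 0.17, intron = 0.17)
)

# InDel length spectra: insertions 1-20 nt, deletions 1-10 nt, mostly 1 nt
.ins_len_prob <- c(0.62, 0.15, 0.08, rep(0.15 / 17, 17))
.del_len_prob <- c(0.62, 0.15, 0.08, rep(0.15 / 7, 7))

#' Plant per-cultivar variant calls with ground truth
#'
#' Plants (a) group-differentiating variants of all four classes at chosen
#' region/effect labels (promoter, synonymous, non-synonymous, stop-gain,
#' start-loss, frameshift, splice-junction, intron, UTR, intergenic);
#' (b) confounders shared by all four cultivars or polymorphic within a
#' group; (c) sites given depth below the filter threshold in one cultivar;
#' and (d) clusters of three SNPs within a 10-bp window that the density
#' filter must remove. True calls are emitted with depth >= 10 and alternate
#' fraction >= 0.9; genotypes are homozygous single-allele calls per cultivar.
#'
#' @param cfg a [synth_config()].
#' @param genome genome as returned (updated) by [generate_gene_models()].
#' @param genes list of gene models.
#' @return list with `calls` (data.frame: chrom, pos, ref, alt, cultivar,
#'   depth, alt_fraction; 0-based positions), `coverage` (data.frame: chrom,
#'   pos, cultivar, depth at every planted site) and `truth` (list with the
#'   planted `variants` table and per-gene `gene_evidence` flags).
#' @export
plant_variants <- function(cfg, genome, genes) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  groups <- cultivar_groups()
  cultivars <- c(groups$small, groups$large)

  chrom_len <- nchar(genome)
  occ <- lapply(chrom_len, function(L) logical(L))

  is_free <- function(chrom, s, e, pad = 12L) {
    L <- chrom_len[[chrom]]
    lo <- max(0L, s - pad); hi <- min(L, e + pad)
    if (s < 0L || e > L) return(FALSE)
    !any(occ[[chrom]][(lo + 1L):hi])
  }
  reserve <- function(chrom, s, e, pad = 12L) {
    L <- chrom_len[[chrom]]
    lo <- max(0L, s - pad); hi <- min(L, e + pad)
    occ[[chrom]][(lo + 1L):hi] <<- TRUE
  }

  # ---- geometry caches --------------------------------------------------
  gpos_list <- lapply(genes, cds_positions)
  cds_seq_list <- lapply(genes, gene_cds_seq, genome = genome)
  introns_list <- lapply(genes, gene_introns)
  utr_runs_list <- lapply(genes, function(g) {
    ex <- g$exons[order(g$exons$start), , drop = FALSE]
    cd <- g$cds[order(g$cds$start), , drop = FALSE]
    runs <- list()
    for (i in seq_len(nrow(ex))) {
      s <- ex$start[i]; e <- ex$end[i]
      inside <- cd[cd$start < e & cd$end > s, , drop = FALSE]
      cur <- s
      for (j in seq_len(nrow(inside))) {
        if (inside$start[j] > cur) runs[[length(runs) + 1L]] <-
            c(cur, inside$start[j])
        cur <- max(cur, inside$end[j])
      }
      if (cur < e) runs[[length(runs) + 1L]] <- c(cur, e)
    }
    if (!length(runs)) return(data.frame(start = integer(0), end = integer(0)))
    m <- do.call(rbind, runs)
    data.frame(start = m[, 1], end = m[, 2])
  })

  # intergenic intervals: complement of genes plus their promoter windows
  intergenic <- lapply(names(genome), function(ch) {
    L <- chrom_len[[ch]]
    gs <- Filter(function(g) g$chrom == ch, genes)
    if (!length(gs)) {
      return(data.frame(start = 200L, end = L - 200L))
    }
    blk <- t(vapply(gs, function(g) {
      s <- g$start - if (g$strand == "+") 2100L else 100L
      e <- g$end + if (g$strand == "-") 2100L else 100L
      c(max(0L, s), min(L, e))
    }, numeric(2)))
    blk <- blk[order(blk[, 1]), , drop = FALSE]
    out <- list(); cur <- 200L
    for (i in seq_len(nrow(blk))) {
      if (blk[i, 1] > cur + 50L) out[[length(out) + 1L]] <- c(cur, blk[i, 1])
      cur <- max(cur, blk[i, 2])
    }
    if (cur + 50L < L - 200L) out[[length(out) + 1L]] <- c(cur, L - 200L)
    m <- do.call(rbind, out)
    data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  })
  names(intergenic) <- names(genome)

  rows <- list()
  add_row <- function(chrom, pos, ref, alt, class, region, effect,
                      subtype = NA_character_, gene_id = NA_character_,
                      small_allele = ref, large_allele = alt,
                      expect = "kept") {
    rows[[length(rows) + 1L]] <<- list(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      class = class, region = region, effect = effect, subtype = subtype,
      gene_id = gene_id, small_allele = small_allele,
      large_allele = large_allele, expect = expect)
  }

  rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")
  other_base <- function(b) resample(setdiff(BASES, b))
  # substitutions with the transition excess seen in resequencing data
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  mut_base <- function(b) {
    if (runif(1) < 0.63) unname(transition_of[b]) else
      resample(setdiff(BASES, c(b, transition_of[b])))
  }
  tx_alt_fwd <- function(strand, b) if (strand == "+") b else unname(.comp[b])

  # ---- intergenic / promoter / intron position samplers -----------------
  sample_intergenic <- function(span, tries = 400L) {
    for (t in seq_len(tries)) {
      ch <- resample(names(genome))
      iv <- intergenic[[ch]]
      if (!nrow(iv)) next
      w <- pmax(iv$end - iv$start - span, 0)
      if (sum(w) == 0) next
      i <- resample(seq_len(nrow(iv)), prob = w)
      pos <- iv$start[i] + sample.int(iv$end[i] - iv$start[i] - span, 1L) - 1L
      if (is_free(ch, pos, pos + span)) return(list(chrom = ch, pos = pos))
    }
    NULL
  }
  sample_promoter <- function(span, tries = 400L) {
    for (t in seq_len(tries)) {
      g <- genes[[resample(seq_along(genes))]]
      off <- sample((60L + span):1900L, 1L)
      pos <- if (g$strand == "+") g$start - off else g$end + off - span
      if (is_free(g$chrom, pos, pos + span)) {
        return(list(chrom = g$chrom, pos = pos, gene_id = g$gene_id))
      }
    }
    NULL
  }
  sample_intron <- function(span, tries = 400L) {
    for (t in seq_len(tries)) {
      gi <- resample(seq_along(genes))
      g <- genes[[gi]]
      intr <- introns_list[[gi]]
      if (!nrow(intr)) next
      i <- resample(seq_len(nrow(intr)))
      lo <- intr$start[i] + 4L
      hi <- intr$end[i] - 4L - span
      if (hi <= lo) next
      pos <- sample(lo:hi, 1L)
      if (is_free(g$chrom, pos, pos + span)) {
        return(list(chrom = g$chrom, pos = pos, gene_id = g$gene_id))
      }
    }
    NULL
  }
  sample_utr <- function(span, tries = 400L) {
    for (t in seq_len(tries)) {
      gi <- resample(seq_along(genes))
      g <- genes[[gi]]
      ur <- utr_runs_list[[gi]]
      ok <- ur[ur$end - ur$start >= span + 6L, , drop = FALSE]
      if (!nrow(ok)) next
      i <- resample(seq_len(nrow(ok)))
      lo <- ok$start[i] + 3L
      hi <- ok$end[i] - 3L - span
      if (hi < lo) next
      pos <- if (hi == lo) lo else sample(lo:hi, 1L)
      if (is_free(g$chrom, pos, pos + span)) {
        return(list(chrom = g$chrom, pos = pos, gene_id = g$gene_id))
      }
    }
    NULL
  }

  # ---- allele builders for non-coding sites -----------------------------
  make_alleles <- function(class, chrom, pos) {
    switch(class,
      SNP = {
        ref <- base_at(genome, chrom, pos)
        list(ref = ref, alt = mut_base(ref), span = 1L)
      },
      MNP = {
        m <- resample(2:3)
        ref <- base_at(genome, chrom, pos, m)
        rb <- strsplit(ref, "")[[1]]
        ab <- rb
        ab[1L] <- other_base(rb[1L])
        ab[m] <- other_base(rb[m])
        list(ref = ref, alt = paste(ab, collapse = ""), span = m)
      },
      InDel = {
        if (runif(1) < 0.55) {
          d <- sample(1:20, 1L, prob = .ins_len_prob)
          ref <- base_at(genome, chrom, pos)
          list(ref = ref, alt = paste0(ref, rand_bases(d)), span = 1L)
        } else {
          d <- sample(1:10, 1L, prob = .del_len_prob)
          ref <- base_at(genome, chrom, pos, d + 1L)
          list(ref = ref, alt = substr(ref, 1L, 1L), span = d + 1L)
        }
      },
      complex = {
        if (runif(1) < 0.5) {
          ref <- base_at(genome, chrom, pos, 3L)
          rb <- strsplit(ref, "")[[1]]
          alt <- paste0(other_base(rb[1L]), other_base(rb[3L]))
          list(ref = ref, alt = alt, span = 3L)
        } else {
          ref <- base_at(genome, chrom, pos, 2L)
          rb <- strsplit(ref, "")[[1]]
          alt <- paste0(other_base(rb[1L]), resample(BASES),
                        other_base(rb[1L]), resample(BASES))
          list(ref = ref, alt = alt, span = 2L)
        }
      })
  }

  # span reserved before alleles are known: use the maximum ref span per class
  class_span <- c(SNP = 1L, MNP = 3L, InDel = 11L, complex = 3L)

  plant_noncoding <- function(class, region, n) {
    sampler <- switch(region, intergenic = sample_intergenic,
                      promoter = sample_promoter, intron = sample_intron,
                      utr = sample_utr)
    for (i in seq_len(n)) {
      hit <- sampler(class_span[[class]])
      if (is.null(hit)) {
        stop("generation error: could not place ", class, " in ", region)
      }
      al <- make_alleles(class, hit$chrom, hit$pos)
      small <- al$ref; large <- al$alt
      if (region == "intergenic") {
        u <- runif(1)
        if (u < 0.03 && class == "SNP") {
          small <- resample(setdiff(BASES, c(al$ref, al$alt)))
        } else if (u < 0.13) {
          small <- al$alt; large <- al$ref
        }
      }
      add_row(hit$chrom, hit$pos, al$ref, al$alt, class,
              region = if (region == "utr") "exon" else region,
              effect = "non_coding",
              gene_id = hit$gene_id %||% NA_character_,
              small_allele = small, large_allele = large)
      reserve(hit$chrom, hit$pos, hit$pos + al$span)
    }
  }

  # ---- coding planters --------------------------------------------------
  contiguous3 <- function(p) {
    (p[3L] == p[1L] + 2L) || (p[3L] == p[1L] - 2L)
  }
  ct <- codon_table()

  plant_codon_snp <- function(kind, n) {
    used_start <- character(0)
    for (v in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(600L)) {
        gi <- resample(seq_along(genes))
        g <- genes[[gi]]
        gpos <- gpos_list[[gi]]
        cseq <- cds_seq_list[[gi]]
        n_cod <- nchar(cseq) / 3L
        if (kind == "start_loss") {
          if (g$gene_id %in% used_start) next
          ti <- resample(1:3)
          refb <- substr(cseq, ti, ti)
          newb <- other_base(refb)
        } else {
          j <- resample(2:(n_cod - 1L))
          cod <- substr(cseq, 3L * j - 2L, 3L * j)
          cb <- strsplit(cod, "")[[1]]
          cand <- NULL
          for (ci in resample(1:3, 3L)) {
            for (b in resample(BASES, 4L)) {
              if (b == cb[ci]) next
              nb <- cb; nb[ci] <- b
              ncod <- paste(nb, collapse = "")
              ok <- switch(kind,
                synonymous = !(ncod %in% STOP_CODONS) &&
                  ct[[ncod]] == ct[[cod]],
                non_synonymous = !(ncod %in% STOP_CODONS) &&
                  ct[[ncod]] != ct[[cod]],
                stop_gain = ncod %in% STOP_CODONS)
              if (ok) { cand <- list(ci = ci, b = b); break }
            }
            if (!is.null(cand)) break
          }
          if (is.null(cand)) next
          ti <- 3L * (j - 1L) + cand$ci
          refb <- substr(cseq, ti, ti)
          newb <- cand$b
        }
        p <- gpos[ti]
        if (!is_free(g$chrom, p, p + 1L)) next
        ref_f <- base_at(genome, g$chrom, p)
        alt_f <- tx_alt_fwd(g$strand, newb)
        stopifnot(ref_f == tx_alt_fwd(g$strand, refb), ref_f != alt_f)
        eff <- switch(kind, synonymous = "synonymous",
                      non_synonymous = "non_synonymous",
                      start_loss = "large_effect", stop_gain = "large_effect")
        sub <- switch(kind, start_loss = "start_loss",
                      stop_gain = "stop_gain", NA_character_)
        add_row(g$chrom, p, ref_f, alt_f, "SNP", "exon", eff, sub, g$gene_id)
        reserve(g$chrom, p, p + 1L)
        if (kind == "start_loss") used_start <- c(used_start, g$gene_id)
        placed <- TRUE
        break
      }
      if (!placed) stop("generation error: could not plant ", kind, " SNP")
    }
  }

  plant_splice <- function(n) {
    for (v in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(400L)) {
        gi <- resample(seq_along(genes))
        g <- genes[[gi]]
        intr <- introns_list[[gi]]
        if (!nrow(intr)) next
        i <- resample(seq_len(nrow(intr)))
        p <- resample(c(intr$start[i], intr$start[i] + 1L,
                        intr$end[i] - 2L, intr$end[i] - 1L))
        if (!is_free(g$chrom, p, p + 1L)) next
        ref <- base_at(genome, g$chrom, p)
        add_row(g$chrom, p, ref, other_base(ref), "SNP", "intron",
                "large_effect", "splice_site", g$gene_id)
        reserve(g$chrom, p, p + 1L)
        placed <- TRUE
        break
      }
      if (!placed) stop("generation error: could not plant splice variant")
    }
  }

  plant_frameshift <- function(n) {
    for (v in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(400L)) {
        gi <- resample(seq_along(genes))
        g <- genes[[gi]]
        segs <- g$cds[order(g$cds$start), , drop = FALSE]
        segs <- segs[segs$end - segs$start >= 30L, , drop = FALSE]
        if (!nrow(segs)) next
        si <- resample(seq_len(nrow(segs)))
        d <- resample(1:2)
        a <- sample((segs$start[si] + 5L):(segs$end[si] - 6L - d), 1L)
        gpos <- gpos_list[[gi]]
        crit <- c(gpos[1:3], tail(gpos, 3L))
        if (any(crit >= a - 6L & crit <= a + d + 6L)) next
        if (!is_free(g$chrom, a, a + d + 1L)) next
        if (runif(1) < 0.6) {
          ref <- base_at(genome, g$chrom, a, d + 1L)
          alt <- substr(ref, 1L, 1L)
        } else {
          ref <- base_at(genome, g$chrom, a)
          alt <- paste0(ref, rand_bases(d))
        }
        add_row(g$chrom, a, ref, alt, "InDel", "exon", "large_effect",
                "frameshift", g$gene_id)
        reserve(g$chrom, a, a + d + 1L)
        placed <- TRUE
        break
      }
      if (!placed) stop("generation error: could not plant frameshift")
    }
  }

  plant_inframe_del <- function(n) {
    for (v in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(400L)) {
        gi <- resample(seq_along(genes))
        g <- genes[[gi]]
        gpos <- gpos_list[[gi]]
        n_cod <- length(gpos) / 3L
        j <- resample(3:(n_cod - 2L))
        p <- gpos[(3L * j - 2L):(3L * j)]
        if (!contiguous3(p)) next
        lo <- min(p)
        anchor <- lo - 1L
        # anchor must sit in the same CDS segment (not in an intron)
        seg <- g$cds[g$cds$start <= anchor & g$cds$end > anchor, , drop = FALSE]
        if (!nrow(seg) || seg$end[1L] < lo + 3L) next
        if (!is_free(g$chrom, anchor, anchor + 4L)) next
        ref <- base_at(genome, g$chrom, anchor, 4L)
        add_row(g$chrom, anchor, ref, substr(ref, 1L, 1L), "InDel", "exon",
                "non_synonymous", NA_character_, g$gene_id)
        reserve(g$chrom, anchor, anchor + 4L)
        placed <- TRUE
        break
      }
      if (!placed) stop("generation error: could not plant in-frame deletion")
    }
  }

  plant_codon_mnp <- function(kind, n) {
    for (v in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(800L)) {
        gi <- resample(seq_along(genes))
        g <- genes[[gi]]
        gpos <- gpos_list[[gi]]
        cseq <- cds_seq_list[[gi]]
        n_cod <- nchar(cseq) / 3L
        j <- resample(2:(n_cod - 1L))
        p <- gpos[(3L * j - 2L):(3L * j)]
        if (!contiguous3(p)) next
        cod <- substr(cseq, 3L * j - 2L, 3L * j)
        hamming <- function(x, y) {
          sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
        }
        if (kind == "synonymous") {
          syn <- setdiff(names(ct)[ct == ct[[cod]]], c(cod, STOP_CODONS))
          syn <- syn[vapply(syn, hamming, numeric(1), x = cod) >= 2]
          if (!length(syn)) next
          ncod <- resample(syn)
        } else {
          alt_pool <- setdiff(nonstop_codons(), names(ct)[ct == ct[[cod]]])
          alt_pool <- alt_pool[vapply(alt_pool, hamming, numeric(1),
                                      x = cod) >= 2]
          ncod <- resample(alt_pool)
        }
        lo <- min(p)
        if (!is_free(g$chrom, lo, lo + 3L)) next
        ref_f <- base_at(genome, g$chrom, lo, 3L)
        alt_f <- if (g$strand == "+") ncod else revcomp(ncod)
        add_row(g$chrom, lo, ref_f, alt_f, "MNP", "exon",
                if (kind == "synonymous") "synonymous" else "non_synonymous",
                NA_character_, g$gene_id)
        reserve(g$chrom, lo, lo + 3L)
        placed <- TRUE
        break
      }
      if (!placed) stop("generation error: could not plant codon MNP")
    }
  }

  # ---- plant everything -------------------------------------------------
  for (cls in names(cfg$n_diff_variants)) {
    counts <- alloc_counts(cfg$n_diff_variants[[cls]], .region_fracs[[cls]])
    if (cls == "SNP") {
      plant_codon_snp("start_loss", min(counts[["start_loss"]],
                                        length(genes)))
      plant_splice(counts[["splice_site"]])
      plant_codon_snp("stop_gain", counts[["stop_gain"]])
      plant_codon_snp("synonymous", counts[["synonymous"]])
      plant_codon_snp("non_synonymous", counts[["non_synonymous"]])
    }
    if (cls == "MNP") {
      plant_codon_mnp("synonymous", counts[["synonymous"]])
      plant_codon_mnp("non_synonymous", counts[["non_synonymous"]])
    }
    if (cls == "InDel") {
      plant_frameshift(counts[["frameshift"]])
      plant_inframe_del(counts[["inframe"]])
    }
    if ("utr" %in% names(counts)) plant_noncoding(cls, "utr", counts[["utr"]])
    plant_noncoding(cls, "promoter", counts[["promoter"]])
    plant_noncoding(cls, "intron", counts[["intron"]])
    plant_noncoding(cls, "intergenic", counts[["intergenic"]])
  }

  # density clusters: three SNPs spanning 9 bp (all must be removed)
  for (k in seq_len(cfg$n_density_clusters)) {
    hit <- sample_intergenic(10L)
    if (is.null(hit)) stop("generation error: could not place density cluster")
    for (off in c(0L, 4L, 9L)) {
      p <- hit$pos + off
      ref <- base_at(genome, hit$chrom, p)
      add_row(hit$chrom, p, ref, other_base(ref), "SNP", "intergenic",
              "non_coding", expect = "density_removed")
    }
    reserve(hit$chrom, hit$pos, hit$pos + 10L)
  }

  # confounders
  conf <- alloc_counts(cfg$n_confound_variants,
                       c(shared_all = 0.4, within_group = 0.4, low_af = 0.2))
  conf_alleles <- list()
  for (kind in names(conf)) {
    for (k in seq_len(conf[[kind]])) {
      hit <- sample_intergenic(1L)
      if (is.null(hit)) stop("generation error: could not place confounder")
      ref <- base_at(genome, hit$chrom, hit$pos)
      alt <- other_base(ref)
      idx <- length(rows) + 1L
      if (kind == "shared_all") {
        add_row(hit$chrom, hit$pos, ref, alt, "SNP", "intergenic",
                "non_coding", small_allele = alt, large_allele = alt,
                expect = "not_differentiating")
        conf_alleles[[idx]] <- setNames(rep(alt, 4L), cultivars)
      } else if (kind == "within_group") {
        carrier <- resample(cultivars)
        al <- setNames(rep(ref, 4L), cultivars)
        al[[carrier]] <- alt
        add_row(hit$chrom, hit$pos, ref, alt, "SNP", "intergenic",
                "non_coding", small_allele = ref, large_allele = ref,
                expect = "not_differentiating")
        conf_alleles[[idx]] <- al
      } else { # low_af: a large-group cultivar fails the 0.9 fraction filter
        add_row(hit$chrom, hit$pos, ref, alt, "SNP", "intergenic",
                "non_coding", expect = "low_af_removed")
      }
      reserve(hit$chrom, hit$pos, hit$pos + 1L)
    }
  }

  truth <- as.data.frame(data.table::rbindlist(rows))
  truth$pos <- as.integer(truth$pos)

  # per-cultivar alleles
  al_mat <- matrix(NA_character_, nrow(truth), 4L,
                   dimnames = list(NULL, cultivars))
  for (i in seq_len(nrow(truth))) {
    ca <- conf_alleles[i][[1]]
    if (!is.null(ca)) {
      al_mat[i, ] <- ca[cultivars]
    } else {
      al_mat[i, groups$small] <- truth$small_allele[i]
      al_mat[i, groups$large] <- truth$large_allele[i]
    }
  }

  # low-depth exclusions among kept bulk non-coding differentiating variants
  low_cult <- rep(NA_character_, nrow(truth))
  low_type <- rep(NA_character_, nrow(truth))
  pool <- which(truth$expect == "kept" &
                  truth$region %in% c("intergenic", "intron"))
  n_low <- floor(cfg$fraction_low_depth * length(pool))
  if (n_low > 0) {
    sel <- resample(pool, n_low)
    truth$expect[sel] <- "low_depth_removed"
    for (i in sel) {
      cu <- resample(cultivars)
      low_cult[i] <- cu
      low_type[i] <- if (al_mat[i, cu] != truth$ref[i]) "dp" else "cov"
    }
  }

  af_low <- truth$expect == "low_af_removed"
  af_cult <- ifelse(af_low, resample(groups$large, nrow(truth),
                                     replace = TRUE), NA_character_)

  # ---- emit calls and the coverage track --------------------------------
  call_rows <- list()
  cov_rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (cu in cultivars) {
      carries <- al_mat[i, cu] != truth$ref[i]
      if (carries) {
        dp <- if (!is.na(low_cult[i]) && low_cult[i] == cu &&
                  low_type[i] == "dp") sample(3:9, 1L) else sample(20:60, 1L)
        af <- if (!is.na(af_cult[i]) && af_cult[i] == cu) 0.5 else
          round(runif(1, 0.92, 1.0), 3)
        call_rows[[length(call_rows) + 1L]] <- list(
          chrom = truth$chrom[i], pos = truth$pos[i], ref = truth$ref[i],
          alt = al_mat[i, cu], cultivar = cu, depth = dp, alt_fraction = af)
        cov <- dp
      } else {
        cov <- if (!is.na(low_cult[i]) && low_cult[i] == cu &&
                   low_type[i] == "cov") sample(3:9, 1L) else sample(20:60, 1L)
      }
      cov_rows[[length(cov_rows) + 1L]] <- list(
        chrom = truth$chrom[i], pos = truth$pos[i], cultivar = cu,
        depth = cov)
    }
  }
  calls <- as.data.frame(data.table::rbindlist(call_rows))
  coverage <- as.data.frame(data.table::rbindlist(cov_rows))
  calls <- calls[order(calls$cultivar, calls$chrom, calls$pos), ]
  coverage <- coverage[order(coverage$cultivar, coverage$chrom,
                             coverage$pos), ]
  rownames(calls) <- rownames(coverage) <- NULL

  o <- order(truth$chrom, truth$pos)
  truth <- truth[o, ]
  al_mat <- al_mat[o, , drop = FALSE]
  rownames(truth) <- NULL
  for (cu in cultivars) truth[[paste0("allele_", cu)]] <- al_mat[, cu]

  kept <- truth[truth$expect == "kept", ]
  ev_genes <- sort(unique(kept$gene_id[!is.na(kept$gene_id) &
    (kept$region == "promoter" | kept$effect %in%
       c("non_synonymous", "large_effect"))]))
  gene_evidence <- data.frame(
    gene_id = ev_genes,
    has_promoter_poly = vapply(ev_genes, function(g) {
      any(kept$gene_id == g & kept$region == "promoter", na.rm = TRUE)
    }, logical(1)),
    has_nonsyn = vapply(ev_genes, function(g) {
      any(kept$gene_id == g & kept$effect == "non_synonymous", na.rm = TRUE)
    }, logical(1)),
    has_large_effect = vapply(ev_genes, function(g) {
      any(kept$gene_id == g & kept$effect == "large_effect", na.rm = TRUE)
    }, logical(1)),
    row.names = NULL)

  list(calls = calls, coverage = coverage,
       truth = list(variants = truth, gene_evidence = gene_evidence))
}
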