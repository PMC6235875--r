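# Region assignment, substitution spectra, window densities and highly
# polymorphic gene outliers.

#' Assign genomic regions to variants
#'
#' Labels each variant exon, intron, promoter (within `promoter_bp` upstream
#' of a transcription start, strand-aware) or intergenic, using the reference
#' span of the variant. Precedence: exon > intron > promoter > intergenic.
#' Ties between genes at equal precedence are broken by nearest TSS, then by
#' gene id.
#'
#' @param variants data.frame with chrom, pos (0-based) and ref.
#' @param genes list of gene models.
#' @param promoter_bp promoter width upstream of the TSS (default 2000).
#' @return `variants` with `region` and `gene_id` columns added.
#' @export
assign_region <- function(variants, genes, promoter_bp = 2000L) {
  n <- nrow(variants)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (!n || !length(genes)) {
    variants$region <- region
    variants$gene_id <- gene_id
    return(variants)
  }
  gchrom <- vapply(genes, `[[`, character(1), "chrom")
  gid <- vapply(genes, `[[`, character(1), "gene_id")
  tss <- vapply(genes, function(g) {
    if (g$strand == "+") g$start else g$end - 1L
  }, numeric(1))

  vstart <- variants$pos
  vend <- variants$pos + nchar(variants$ref)

  pick <- function(cands, vpos) {
    if (length(cands) == 1L) return(cands)
    d <- abs(tss[cands] - vpos)
    cands <- cands[d == min(d)]
    cands[order(gid[cands])][1]
  }

  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    gi <- which(gchrom == ch)
    if (!length(gi)) next
    v_ir <- IRanges::IRanges(start = vstart[vi] + 1L, end = vend[vi])
    exon_ir <- IRanges::IRanges(
      start = unlist(lapply(gi, function(k) genes[[k]]$exons$start)) + 1L,
      end = unlist(lapply(gi, function(k) genes[[k]]$exons$end)))
    exon_gene <- unlist(lapply(gi, function(k) {
      rep(k, nrow(genes[[k]]$exons))
    }))
    span_ir <- IRanges::IRanges(
      start = vapply(gi, function(k) genes[[k]]$start, numeric(1)) + 1L,
      end = vapply(gi, function(k) genes[[k]]$end, numeric(1)))
    prom_ir <- IRanges::IRanges(
      start = vapply(gi, function(k) {
        g <- genes[[k]]
        if (g$strand == "+") g$start - promoter_bp else g$end
      }, numeric(1)) + 1L,
      end = vapply(gi, function(k) {
        g <- genes[[k]]
        if (g$strand == "+") g$start else g$end + promoter_bp
      }, numeric(1)))

    ov_ex <- IRanges::findOverlaps(v_ir, exon_ir)
    ov_sp <- IRanges::findOverlaps(v_ir, span_ir)
    ov_pr <- IRanges::findOverlaps(v_ir, prom_ir)
    ex_by_v <- split(exon_gene[S4Vectors::subjectHits(ov_ex)],
                     S4Vectors::queryHits(ov_ex))
    sp_by_v <- split(gi[S4Vectors::subjectHits(ov_sp)],
                     S4Vectors::queryHits(ov_sp))
    pr_by_v <- split(gi[S4Vectors::subjectHits(ov_pr)],
                     S4Vectors::queryHits(ov_pr))
    for (q in seq_along(vi)) {
      i <- vi[q]
      qk <- as.character(q)
      if (!is.null(ex_by_v[[qk]])) {
        region[i] <- "exon"
        gene_id[i] <- gid[pick(unique(ex_by_v[[qk]]), vstart[i])]
      } else if (!is.null(sp_by_v[[qk]])) {
        region[i] <- "intron"
        gene_id[i] <- gid[pick(unique(sp_by_v[[qk]]), vstart[i])]
      } else if (!is.null(pr_by_v[[qk]])) {
        region[i] <- "promoter"
        gene_id[i] <- gid[pick(unique(pr_by_v[[qk]]), vstart[i])]
      }
    }
  }
  variants$region <- region
  variants$gene_id <- gene_id
  variants
}

#' Transition/transversion counts for SNPs
#'
#' @param ref,alt single-base allele vectors (SNP class only).
#' @return list with `transitions`, `transversions` and a per-substitution
#'   `by_type` table (unordered base pairs).
#' @export
ts_tv <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("validation error: ts_tv expects SNP alleles")
  }
  if (any(ref == alt)) stop("validation error: identical alleles")
  pair <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  is_ts <- pair %in% c("A/G", "C/T")
  list(transitions = sum(is_ts), transversions = sum(!is_ts),
       by_type = table(pair))
}

#' InDel length spectrum
#'
#' Length is the absolute allele-length difference; an event is an insertion
#' when the substituted (group) allele is longer than the reference.
#'
#' @param ref,alt allele vectors of InDel-class variants.
#' @return data.frame with `type` (insertion/deletion), `length` and `count`.
#' @export
indel_spectrum <- function(ref, alt) {
  d <- nchar(alt) - nchar(ref)
  if (any(d == 0L)) {
    stop("validation error: zero length difference in InDel input")
  }
  type <- ifelse(d > 0L, "insertion", "deletion")
  tab <- as.data.frame(table(type = type, length = abs(d)),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  data.frame(type = tab$type, length = as.integer(tab$length),
             count = tab$Freq, row.names = NULL)
}

#' Variant frequency per fixed-width genomic window
#'
#' Tiles each chromosome from position 0 with `window_bp` windows (the last
#' partial tile is kept, its frequency normalized by its actual length) and
#' reports counts and frequency per `window_bp`. Chromosome-level frequency is
#' count / chromosome length x `window_bp`.
#'
#' @param variants data.frame with chrom and pos (0-based); a `class` column,
#'   if present, is tabulated per window.
#' @param genome named character vector (for chromosome lengths).
#' @param window_bp window width (default 100 kb).
#' @return list with `windows` and `chromosomes` data.frames.
#' @export
window_frequency <- function(variants, genome, window_bp = 100000L) {
  classes <- if ("class" %in% names(variants)) {
    sort(unique(variants$class))
  } else character(0)
  win_rows <- list()
  chrom_rows <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    starts <- seq.int(0L, L - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, L)
    v <- variants[variants$chrom == ch, , drop = FALSE]
    idx <- findInterval(v$pos, starts)
    count <- tabulate(idx, nbins = length(starts))
    row <- data.frame(chrom = ch, start = starts, end = ends, count = count,
                      frequency = count / (ends - starts) * window_bp)
    for (cl in classes) {
      row[[paste0("n_", cl)]] <- tabulate(idx[v$class == cl],
                                          nbins = length(starts))
    }
    win_rows[[ch]] <- row
    chrom_rows[[ch]] <- data.frame(chrom = ch, count = nrow(v),
                                   frequency = nrow(v) / L * window_bp)
  }
  list(windows = do.call(rbind, c(win_rows, list(make.row.names = FALSE))),
       chromosomes = do.call(rbind, c(chrom_rows,
                                      list(make.row.names = FALSE))))
}

#' Per-gene polymorphism counts and genic densities
#'
#' Counts annotated variants per gene by region and consequence and computes
#' per-kb densities over the gene's exonic and intronic spans.
#'
#' @param annotated data.frame from [annotate_variants()].
#' @param genes list of gene models.
#' @return data.frame with one row per gene carrying at least one variant.
#' @export
gene_variant_summary <- function(annotated, genes) {
  gid <- vapply(genes, `[[`, character(1), "gene_id")
  exon_kb <- vapply(genes, function(g) {
    sum(g$exons$end - g$exons$start) / 1000
  }, numeric(1))
  intron_kb <- vapply(genes, function(g) {
    intr <- gene_introns(g)
    sum(intr$end - intr$start) / 1000
  }, numeric(1))
  ann <- annotated[!is.na(annotated$gene_id), , drop = FALSE]
  genes_hit <- sort(unique(ann$gene_id))
  rows <- lapply(genes_hit, function(g) {
    a <- ann[ann$gene_id == g, ]
    k <- match(g, gid)
    n_ex <- sum(a$region == "exon")
    n_in <- sum(a$region == "intron")
    data.frame(
      gene_id = g,
      n_promoter = sum(a$region == "promoter"),
      n_exon = n_ex,
      n_intron = n_in,
      n_synonymous = sum(a$consequence == "synonymous"),
      n_non_synonymous = sum(a$consequence == "non_synonymous"),
      n_large_effect = sum(a$consequence == "large_effect"),
      exon_kb = exon_kb[k],
      intron_kb = intron_kb[k],
      exonic_density = n_ex / exon_kb[k],
      intronic_density = if (intron_kb[k] > 0) n_in / intron_kb[k] else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Highly polymorphic gene outliers by the third-quartile rule
#'
#' Among genes with at least one polymorphism in the chosen genic region,
#' flags those whose per-kb density lies strictly above the third quartile of
#' the density distribution (Q3 by linear interpolation between order
#' statistics, the standard boxplot default).
#'
#' @param summary data.frame from [gene_variant_summary()].
#' @param region `"exonic"` or `"intronic"`.
#' @return list with `genes` (flagged gene ids) and `q3` (the quartile used).
#' @export
polymorphic_gene_outliers <- function(summary,
                                      region = c("exonic", "intronic")) {
  region <- match.arg(region)
  dens <- summary[[paste0(region, "_density")]]
  sel <- dens > 0
  dens <- dens[sel]
  ids <- summary$gene_id[sel]
  if (length(dens) < 4L) {
    stop("insufficient data: need at least 4 genes with polymorphisms in ",
         region, " regions")
  }
  q3 <- unname(quantile(dens, 0.75, type = 7))
  list(genes = ids[dens > q3], q3 = q3)
}
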