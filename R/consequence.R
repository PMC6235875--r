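# Coding-consequence calling by whole-CDS re-substitution in transcript
# orientation. Severity ladder: splice_site > start_loss > frameshift
# (net CDS length change not divisible by 3) > stop_gain (new in-frame stop
# before the native stop) > non_synonymous > synonymous. In-frame InDels that
# do not create a stop are non-synonymous; exonic positions outside the CDS
# (UTRs) and intron interiors are non_coding.

consequence_result <- function(consequence, subtype = NA_character_) {
  list(consequence = consequence, subtype = subtype)
}

#' Coding consequence of a variant on a gene
#'
#' Builds the reference CDS in transcript orientation, substitutes the given
#' allele, and classifies the change as synonymous, non-synonymous or
#' large-effect (frameshift, start-loss, stop-gain, or splice-site when the
#' variant span intersects the first/last `splice_window_bp` bases of an
#' intron).
#'
#' @param chrom,pos,ref,alt the variant (0-based pos; forward-strand alleles;
#'   `alt` is the substituted allele — for group-differentiating variants the
#'   large-group allele when it differs from the reference).
#' @param gene gene model overlapped by the variant.
#' @param genome named character vector of chromosome sequences.
#' @param splice_window_bp intronic splice-junction window width (default 2).
#' @return list with `consequence` (synonymous / non_synonymous /
#'   large_effect / non_coding) and `subtype` (frameshift / start_loss /
#'   stop_gain / splice_site or NA).
#' @export
call_consequence <- function(chrom, pos, ref, alt, gene, genome,
                             splice_window_bp = 2L) {
  if (chrom != gene$chrom || pos + nchar(ref) <= gene$start ||
      pos >= gene$end) {
    stop("contract error: variant does not overlap the gene")
  }
  tr <- trim_alleles(ref, alt)
  s <- pos + tr$offset
  e <- s + nchar(tr$ref)

  # splice junctions first
  intr <- gene_introns(gene)
  for (i in seq_len(nrow(intr))) {
    w1 <- c(intr$start[i], intr$start[i] + splice_window_bp)
    w2 <- c(intr$end[i] - splice_window_bp, intr$end[i])
    if ((s < w1[2] && e > w1[1]) || (s < w2[2] && e > w2[1])) {
      return(consequence_result("large_effect", "splice_site"))
    }
  }

  gpos <- cds_positions(gene)
  cds_seq <- gene_cds_seq(gene, genome)
  if (nchar(cds_seq) %% 3L != 0L) {
    stop("model error: CDS length not divisible by 3 for ", gene$gene_id)
  }

  minus <- gene$strand == "-"
  if (nchar(tr$ref) == 0L) {
    # pure insertion between s-1 and s: coding only when both flanks are
    # transcript-adjacent CDS bases
    iL <- match(s - 1L, gpos)
    iR <- match(s, gpos)
    if (is.na(iL) || is.na(iR) || abs(iL - iR) != 1L) {
      return(consequence_result("non_coding"))
    }
    at <- min(iL, iR)   # insert after this transcript index
    ins <- if (minus) revcomp(tr$alt) else tr$alt
    alt_cds <- paste0(substr(cds_seq, 1L, at), ins,
                      substr(cds_seq, at + 1L, nchar(cds_seq)))
  } else {
    idx <- match(s:(e - 1L), gpos)
    if (all(is.na(idx))) return(consequence_result("non_coding"))
    if (anyNA(idx)) {
      # partial CDS overlap: clip equal-length substitutions per base;
      # for length-changing variants fall back to the length rule over the
      # clipped span
      if (nchar(tr$ref) == nchar(tr$alt)) {
        keep <- !is.na(idx)
        rb <- strsplit(tr$ref, "")[[1]][keep]
        ab <- strsplit(tr$alt, "")[[1]][keep]
        ti <- idx[keep]
        if (minus) {
          rb <- rev(unname(.comp[rb])); ab <- rev(unname(.comp[ab]))
          ti <- rev(ti)
        }
        cb <- strsplit(cds_seq, "")[[1]]
        stopifnot(all(cb[ti] == rb))
        cb[ti] <- ab
        alt_cds <- paste(cb, collapse = "")
      } else {
        delta <- nchar(tr$alt) - nchar(tr$ref)
        if (delta %% 3L != 0L) {
          return(consequence_result("large_effect", "frameshift"))
        }
        return(consequence_result("non_synonymous"))
      }
    } else {
      t_lo <- min(idx); t_hi <- max(idx)
      repl <- if (minus) revcomp(tr$alt) else tr$alt
      ref_tx <- substr(cds_seq, t_lo, t_hi)
      expect <- if (minus) revcomp(tr$ref) else tr$ref
      stopifnot(ref_tx == expect)
      alt_cds <- paste0(substr(cds_seq, 1L, t_lo - 1L), repl,
                        substr(cds_seq, t_hi + 1L, nchar(cds_seq)))
    }
  }

  classify_cds_change(cds_seq, alt_cds)
}

# severity ladder on reference vs substituted CDS strings
classify_cds_change <- function(ref_cds, alt_cds) {
  if (substr(alt_cds, 1L, 3L) != "ATG") {
    return(consequence_result("large_effect", "start_loss"))
  }
  delta <- nchar(alt_cds) - nchar(ref_cds)
  if (delta %% 3L != 0L) {
    return(consequence_result("large_effect", "frameshift"))
  }
  alt_aa <- aa_vector(alt_cds)
  n_alt <- length(alt_aa)
  first_stop <- which(alt_aa == "*")[1]
  if (!is.na(first_stop) && first_stop < n_alt) {
    return(consequence_result("large_effect", "stop_gain"))
  }
  if (protein_of(alt_cds) == protein_of(ref_cds)) {
    consequence_result("synonymous")
  } else {
    consequence_result("non_synonymous")
  }
}

#' Annotate differentiating variants with region and consequence
#'
#' Adds region labels ([assign_region()]) and, for genic variants, the coding
#' consequence ([call_consequence()]); promoter and intergenic variants and
#' genic variants outside the CDS and splice windows are `non_coding`.
#'
#' @param diff data.frame from [group_differential()] (chrom, pos, ref, alt,
#'   class columns required).
#' @param genes list of gene models.
#' @param genome named character vector of chromosome sequences.
#' @param promoter_bp promoter width (default 2000).
#' @param splice_window_bp splice window (default 2).
#' @return `diff` with `region`, `gene_id`, `consequence`, `subtype` added.
#' @export
annotate_variants <- function(diff, genes, genome, promoter_bp = 2000L,
                              splice_window_bp = 2L) {
  out <- assign_region(diff, genes, promoter_bp)
  out$consequence <- "non_coding"
  out$subtype <- NA_character_
  if (!nrow(out)) return(out)
  gid <- vapply(genes, `[[`, character(1), "gene_id")
  genic <- which(out$region %in% c("exon", "intron"))
  for (i in genic) {
    g <- genes[[match(out$gene_id[i], gid)]]
    cc <- call_consequence(out$chrom[i], out$pos[i], out$ref[i], out$alt[i],
                           g, genome, splice_window_bp)
    out$consequence[i] <- cc$consequence
    out$subtype[i] <- cc$subtype
  }
  out
}
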