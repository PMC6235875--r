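# Readers/writers for FASTA, GFF3, VCF, BED and the tabular files, plus the
# package's coordinate convention: internal coordinates are 0-based half-open
# everywhere; the 1-based inclusive conventions of GFF3/VCF (and the 1-based
# positions of coverage.tsv) are converted exactly once, here.

#' Write a genome to FASTA (60-column wrap)
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector (names truncated at the first space).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  ok <- grepl("^[ACGTN]*$", out)
  if (!all(ok)) stop("parse error: non-ACGTN characters in sequence ",
                     names(out)[!ok][1])
  out
}

#' Write gene models to GFF3 (1-based inclusive, phase on CDS)
#' @param genes list of gene models.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    a <- function(s, e, type, attrs, phase = ".") {
      sprintf("%s\tseedvar\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, s + 1L, e, g$strand, phase, attrs)
    }
    lines <- c(lines,
               a(g$start, g$end, "gene", sprintf("ID=%s", g$gene_id)),
               a(g$start, g$end, "mRNA",
                 sprintf("ID=%s;Parent=%s", g$tx_id, g$gene_id)))
    ex <- g$exons[order(g$exons$start), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, a(ex$start[i], ex$end[i], "exon",
                          sprintf("ID=%s.exon%d;Parent=%s", g$tx_id, i,
                                  g$tx_id)))
    }
    cd <- g$cds[order(g$cds$start), , drop = FALSE]
    for (i in seq_len(nrow(cd))) {
      lines <- c(lines, sprintf(
        "%s\tseedvar\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
        g$chrom, cd$start[i] + 1L, cd$end[i], g$strand, cd$phase[i],
        g$tx_id, g$tx_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects the gene/mRNA/exon/CDS hierarchy written by [write_gff3()] (one
#' transcript per gene). Coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path GFF3 file.
#' @return list of gene models.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  gene_rows <- df[df$type == "gene", ]
  mrna_rows <- df[df$type == "mRNA", ]
  out <- vector("list", nrow(gene_rows))
  for (i in seq_len(nrow(gene_rows))) {
    gid <- gene_rows$ID[i]
    tx <- mrna_rows[mrna_rows$Parent == gid, ]
    if (nrow(tx) != 1L) {
      stop("validation error: expected exactly one mRNA for gene ", gid)
    }
    ex <- df[df$type == "exon" & df$Parent == tx$ID, ]
    cd <- df[df$type == "CDS" & df$Parent == tx$ID, ]
    ex <- ex[order(ex$start), ]
    cd <- cd[order(cd$start), ]
    out[[i]] <- list(
      gene_id = gid, tx_id = tx$ID,
      chrom = as.character(gene_rows$seqnames[i]),
      strand = as.character(gene_rows$strand[i]),
      start = gene_rows$start[i] - 1L, end = gene_rows$end[i],
      exons = data.frame(start = ex$start - 1L, end = ex$end),
      cds = data.frame(start = cd$start - 1L, end = cd$end,
                       phase = as.integer(cd$phase)))
  }
  out
}

#' Write per-cultivar variant calls to VCF v4.2
#'
#' One alternate allele per record; read depth and alternate fraction in the
#' INFO fields DP and AF.
#'
#' @param calls data.frame with chrom, pos (0-based), ref, alt, depth,
#'   alt_fraction.
#' @param path output file.
#' @param contigs optional named vector of chromosome lengths for the header.
#' @export
write_vcf <- function(calls, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs))
           },
           paste0("##INFO=<ID=DP,Number=1,Type=Integer,",
                  "Description=\"Read depth\">"),
           paste0("##INFO=<ID=AF,Number=1,Type=Float,",
                  "Description=\"Alternate allele fraction\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s",
            calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
            as.integer(calls$depth),
            formatC(calls$alt_fraction, format = "f", digits = 3))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read one cultivar's VCF into variant calls
#'
#' Multi-allelic records are rejected: the group-differential logic assumes
#' one alternate allele per cultivar per site.
#'
#' @param path VCF file.
#' @param cultivar cultivar id attached to every call.
#' @param genome optional named character vector to validate chromosome names
#'   and coordinate bounds.
#' @return data.frame with chrom, pos (0-based), ref, alt, cultivar, depth,
#'   alt_fraction.
#' @export
read_vcf <- function(path, cultivar, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      cultivar = character(0), depth = integer(0),
                      alt_fraction = numeric(0)))
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    stop("validation error: multi-allelic record at ",
         fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"])
  }
  dp <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
  af <- suppressWarnings(vcfR::extract.info(v, "AF", as.numeric = TRUE))
  if (anyNA(dp) || anyNA(af)) {
    stop("parse error: missing DP/AF INFO field at record ",
         which(is.na(dp) | is.na(af))[1])
  }
  pos1 <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos1)) {
    stop("parse error: non-numeric POS at record ", which(is.na(pos1))[1])
  }
  out <- data.frame(chrom = fix[, "CHROM"], pos = pos1 - 1L,
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    cultivar = cultivar, depth = as.integer(dp),
                    alt_fraction = af, row.names = NULL)
  if (!is.null(genome)) {
    bad <- !(out$chrom %in% names(genome))
    if (any(bad)) {
      stop("validation error: unknown chromosome ", out$chrom[bad][1])
    }
    oob <- out$pos + nchar(out$ref) > nchar(genome)[out$chrom] | out$pos < 0L
    if (any(oob)) {
      stop("validation error: coordinate out of chromosome bounds at ",
           out$chrom[oob][1], ":", out$pos[oob][1] + 1L)
    }
  }
  out
}

#' Write QTL intervals to BED3+1 (0-based half-open)
#' @param qtls data.frame with chrom, start, end, name.
#' @param path output file.
#' @export
write_bed <- function(qtls, path) {
  data.table::fwrite(qtls[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read QTL intervals from BED3+1
#' @param path BED file.
#' @return data.frame with chrom, start, end (0-based half-open), name.
#' @export
read_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = FALSE,
                                        col.names = c("chrom", "start",
                                                      "end", "name")))
  if (any(df$start >= df$end)) {
    stop("validation error: BED interval with start >= end at line ",
         which(df$start >= df$end)[1])
  }
  df
}

#' Write the FPKM expression matrix to TSV
#' @param expr genes x tissues numeric matrix with dimnames.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read the FPKM expression matrix from TSV
#' @param path TSV with a gene_id column followed by tissue columns.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (anyNA(m)) stop("validation error: missing cells in expression matrix")
  m
}

# coverage.tsv uses 1-based positions on disk, matching the VCF convention
write_coverage <- function(cov, path) {
  out <- cov
  out$pos <- out$pos + 1L
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

read_coverage <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  df$pos <- df$pos - 1L
  df
}
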