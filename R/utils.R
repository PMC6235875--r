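# Low-level helpers shared across modules. Internal coordinates are 0-based
# half-open everywhere; conversion to/from the 1-based inclusive conventions
# of GFF3/VCF happens only in formats.R.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

codon_table <- function() Biostrings::GENETIC_CODE

all_codons <- function() {
  ct <- codon_table()
  names(ct)
}

nonstop_codons <- function() setdiff(all_codons(), STOP_CODONS)

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(unname(.comp[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# amino-acid vector of a CDS string; an incomplete trailing codon is dropped
aa_vector <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(codon_table()[codons])
}

# protein string up to (exclusive) the first stop codon
protein_of <- function(seq) {
  aa <- aa_vector(seq)
  hit <- which(aa == "*")
  if (length(hit)) aa <- aa[seq_len(hit[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Minimal representation of an allele pair
#'
#' Strips the shared suffix, then the shared prefix, of a REF/ALT pair.
#' `offset` is the number of leading bases removed, i.e. the shift of the
#' variant start position. One side may trim to the empty string (a pure
#' insertion or deletion).
#'
#' @param ref,alt allele strings (non-empty, unequal).
#' @return list with `ref`, `alt`, `offset`.
#' @export
trim_alleles <- function(ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) stop("alleles must be non-empty")
  if (ref == alt) stop("ref and alt alleles are identical")
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  off <- 0L
  while (length(r) > 0L && length(a) > 0L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    off <- off + 1L
  }
  list(ref = paste(r, collapse = ""), alt = paste(a, collapse = ""),
       offset = off)
}

base_at <- function(genome, chrom, pos, len = 1L) {
  substr(genome[[chrom]], pos + 1L, pos + len)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
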