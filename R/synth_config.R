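#' Configuration for the synthetic four-cultivar dataset
#'
#' Defines the study conditions emulated by the generator: a miniature
#' reference genome, gene models, per-cultivar variant calls for two
#' small-seeded and two large-seeded cultivars, a 29-tissue FPKM matrix,
#' a differential-expression table and QTL intervals, all with planted
#' ground truth. Defaults give two 2-Mb chromosomes, 200 genes and ~5,000
#' planted group-differentiating variants.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of gene models.
#' @param n_diff_variants named integer vector of planted group-differentiating
#'   variants per class (`SNP`, `MNP`, `InDel`, `complex`).
#' @param n_confound_variants number of planted non-differentiating variants
#'   (shared by all four cultivars, polymorphic within a group, or failing the
#'   alternate-fraction filter).
#' @param fraction_low_depth proportion of planted differentiating sites given
#'   read depth below 10 in one cultivar (expected to be excluded).
#' @param n_seed_specific number of genes planted with a seed-stage expression
#'   peak and tissue-specificity index above 0.6.
#' @param n_qtls number of QTL intervals.
#' @param n_density_clusters number of planted clusters of three SNPs within a
#'   10-bp window (expected to be removed by the density filter).
#' @param expression_noise_sd standard deviation of log2-FPKM noise.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 42L,
                         n_chroms = 2L,
                         chrom_length = 2e6,
                         n_genes = 200L,
                         n_diff_variants = c(SNP = 3800L, MNP = 250L,
                                             InDel = 600L, complex = 350L),
                         n_confound_variants = 300L,
                         fraction_low_depth = 0.04,
                         n_seed_specific = 40L,
                         n_qtls = 8L,
                         n_density_clusters = 20L,
                         expression_noise_sd = 0.25) {
  nd <- c(SNP = 0L, MNP = 0L, InDel = 0L, complex = 0L)
  if (is.null(names(n_diff_variants)) ||
      !all(names(n_diff_variants) %in% names(nd))) {
    stop("invalid config: n_diff_variants must be named with ",
         "SNP/MNP/InDel/complex")
  }
  nd[names(n_diff_variants)] <- as.integer(n_diff_variants)
  counts <- c(n_chroms = n_chroms, n_genes = n_genes, nd,
              n_confound_variants = n_confound_variants,
              n_seed_specific = n_seed_specific, n_qtls = n_qtls,
              n_density_clusters = n_density_clusters)
  if (any(counts < 0)) stop("invalid config: counts must be >= 0")
  if (n_chroms < 1) stop("invalid config: n_chroms must be >= 1")
  if (chrom_length <= 0) stop("invalid config: chrom_length must be positive")
  if (chrom_length < 15000 && n_genes > 0) {
    stop("invalid config: chrom_length must be at least 10x the mean gene ",
         "footprint (~1.5 kb)")
  }
  if (fraction_low_depth < 0 || fraction_low_depth > 1) {
    stop("invalid config: fraction_low_depth must be in [0, 1]")
  }
  if (expression_noise_sd < 0) {
    stop("invalid config: expression_noise_sd must be >= 0")
  }
  if (n_seed_specific > n_genes) {
    stop("invalid config: n_seed_specific exceeds n_genes")
  }
  structure(list(seed = as.integer(seed),
                 n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 n_diff_variants = nd,
                 n_confound_variants = as.integer(n_confound_variants),
                 fraction_low_depth = fraction_low_depth,
                 n_seed_specific = as.integer(n_seed_specific),
                 n_qtls = as.integer(n_qtls),
                 n_density_clusters = as.integer(n_density_clusters),
                 expression_noise_sd = expression_noise_sd),
            class = "synth_config")
}

#' The four cultivars and their seed-size groups
#'
#' Two small-seeded (Himchana 1, Pusa 362) and two large-seeded
#' (JGK 3, PG 0515) chickpea cultivars.
#'
#' @return list with character vectors `small` and `large`.
#' @export
cultivar_groups <- function() {
  list(small = c("Himchana1", "Pusa362"),
       large = c("JGK3", "PG0515"))
}
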