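#' Run the full discovery-to-candidates pipeline
#'
#' Chains site filtering, the density filter, group-differential discovery,
#' region/consequence annotation, substitution and InDel spectra, 100-kb
#' window densities, the seed-specific screen, the S3/S5 DE gate, QTL
#' containment and candidate-gene selection, with a funnel of counts at each
#' stage.
#'
#' @param ds a `synth_dataset` (from [simulate_dataset()] or
#'   [read_dataset()]) or a directory path written by [write_dataset()].
#' @param min_depth,min_alt_fraction site filters (defaults 10, 0.9).
#' @param promoter_bp promoter width (default 2000).
#' @param splice_window_bp splice window (default 2).
#' @param min_fold,max_q DE gate (defaults 2, 0.05).
#' @param tau_threshold seed-specificity threshold (default 0.6).
#' @param expressed_cutoff_fpkm expression floor (default 1).
#' @param qtl_mode QTL containment rule (default "within").
#' @return list with `diff`, `annotated`, `ts_tv`, `indel_spectrum`,
#'   `windows`, `gene_summary`, `specificity`, `de_flags`, `evidence`,
#'   `candidates` and `funnel`.
#' @export
run_pipeline <- function(ds, min_depth = 10, min_alt_fraction = 0.9,
                         promoter_bp = 2000L, splice_window_bp = 2L,
                         min_fold = 2, max_q = 0.05, tau_threshold = 0.6,
                         expressed_cutoff_fpkm = 1, qtl_mode = "within") {
  if (is.character(ds)) ds <- read_dataset(ds)
  groups <- cultivar_groups()

  diff <- group_differential(ds$calls, ds$coverage, groups$small,
                             groups$large, min_depth = min_depth,
                             min_alt_fraction = min_alt_fraction)
  ann <- annotate_variants(diff, ds$genes, ds$genome, promoter_bp,
                           splice_window_bp)
  snps <- ann[ann$class == "SNP", ]
  tstv <- ts_tv(snps$ref, snps$alt)
  indels <- ann[ann$class == "InDel", ]
  spectrum <- indel_spectrum(indels$ref, indels$alt)
  win <- window_frequency(ann, ds$genome)
  gsum <- gene_variant_summary(ann, ds$genes)

  spec <- specificity_screen(ds$expression, ds$tissue_meta,
                             expressed_cutoff_fpkm = expressed_cutoff_fpkm,
                             tau_threshold = tau_threshold)
  de_flags <- s3s5_higher_in_large(ds$de_table, min_fold, max_q)
  ev <- gene_evidence(ann)
  cand <- select_candidates(spec, ev, de_flags, genes = ds$genes,
                            qtls = ds$qtls, categories = ds$categories,
                            qtl_mode = qtl_mode)

  funnel <- c(
    n_calls = nrow(ds$calls),
    n_calls_pass = nrow(filter_calls(ds$calls, min_depth, min_alt_fraction)),
    n_differentiating = nrow(diff),
    n_snp = sum(diff$class == "SNP"),
    n_mnp = sum(diff$class == "MNP"),
    n_indel = sum(diff$class == "InDel"),
    n_complex = sum(diff$class == "complex"),
    n_genes_with_evidence = nrow(ev),
    n_seed_specific = sum(spec$pattern == "seed_specific"),
    n_candidates = nrow(cand$candidates))

  list(diff = diff, annotated = ann, ts_tv = tstv,
       indel_spectrum = spectrum, windows = win, gene_summary = gsum,
       specificity = spec, de_flags = de_flags, evidence = ev,
       candidates = cand, funnel = funnel)
}
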