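#' Simulate a complete four-cultivar dataset with planted ground truth
#'
#' Chains reference generation, gene-model construction, variant planting,
#' expression/DE simulation, QTL placement and functional-category
#' assignment. Deterministic: the same config (including seed) yields
#' byte-identical files from [write_dataset()].
#'
#' @param cfg a [synth_config()].
#' @return an object of class `synth_dataset`: list with `config`, `genome`,
#'   `genes`, `calls`, `coverage`, `expression`, `tissue_meta`, `de_table`,
#'   `qtls`, `categories` and `truth`.
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  genome0 <- generate_reference(cfg)
  gm <- generate_gene_models(cfg, genome0)
  pv <- plant_variants(cfg, gm$genome, gm$genes)
  ex <- generate_expression(cfg, gm$genes, pv$truth)
  qt <- generate_qtls(cfg, gm$genes, focus_genes = ex$truth$candidate_genes)

  set.seed(cfg$seed + 5L)
  gene_ids <- vapply(gm$genes, `[[`, character(1), "gene_id")
  cats <- rep("unassigned", length(gene_ids))
  ev <- ex$truth$gene_evidence$gene_id
  cats[gene_ids %in% ev] <- resample(
    c("cell_cycle", "cell_growth", "endoreduplication",
      "transcription_factor", "other"),
    sum(gene_ids %in% ev), replace = TRUE,
    prob = c(0.1, 0.2, 0.05, 0.35, 0.3))
  categories <- data.frame(gene_id = gene_ids, category = cats)

  truth <- ex$truth
  truth$qtl_members <- qt$members

  structure(list(config = cfg, genome = gm$genome, genes = gm$genes,
                 calls = pv$calls, coverage = pv$coverage,
                 expression = ex$expression, tissue_meta = ex$tissue_meta,
                 de_table = ex$de_table, qtls = qt$qtls,
                 categories = categories, truth = truth),
            class = "synth_dataset")
}

#' Write a simulated dataset to standard-format files
#'
#' Emits `genome.fa` (60-column FASTA), `genes.gff3`, one VCF v4.2 per
#' cultivar (`<cultivar>.vcf`, INFO fields DP and AF), `coverage.tsv`,
#' `expression.tsv`, `tissues.tsv`, `de_table.tsv`, `qtls.bed` (BED3+1),
#' `categories.tsv` and `truth.json`.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$genome, file.path(dir, "genome.fa"))
  write_gff3(ds$genes, file.path(dir, "genes.gff3"))
  for (cu in unique(c(cultivar_groups()$small, cultivar_groups()$large))) {
    write_vcf(ds$calls[ds$calls$cultivar == cu, ],
              file.path(dir, paste0(cu, ".vcf")),
              contigs = nchar(ds$genome))
  }
  write_coverage(ds$coverage, file.path(dir, "coverage.tsv"))
  write_expression(ds$expression, file.path(dir, "expression.tsv"))
  data.table::fwrite(ds$tissue_meta, file.path(dir, "tissues.tsv"),
                     sep = "\t")
  data.table::fwrite(ds$de_table, file.path(dir, "de_table.tsv"), sep = "\t")
  write_bed(ds$qtls, file.path(dir, "qtls.bed"))
  data.table::fwrite(ds$categories, file.path(dir, "categories.tsv"),
                     sep = "\t")
  truth <- ds$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing the emitted files.
#' @return a `synth_dataset`-shaped list (without `config`).
#' @export
read_dataset <- function(dir) {
  cultivars <- unique(c(cultivar_groups()$small, cultivar_groups()$large))
  calls <- do.call(rbind, lapply(cultivars, function(cu) {
    read_vcf(file.path(dir, paste0(cu, ".vcf")), cu)
  }))
  rownames(calls) <- NULL
  ex <- read_expression(file.path(dir, "expression.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(
    genome = read_fasta(file.path(dir, "genome.fa")),
    genes = read_gff3(file.path(dir, "genes.gff3")),
    calls = calls,
    coverage = read_coverage(file.path(dir, "coverage.tsv")),
    expression = ex,
    tissue_meta = as.data.frame(data.table::fread(
      file.path(dir, "tissues.tsv"))),
    de_table = as.data.frame(data.table::fread(
      file.path(dir, "de_table.tsv"))),
    qtls = read_bed(file.path(dir, "qtls.bed")),
    categories = as.data.frame(data.table::fread(
      file.path(dir, "categories.tsv"))),
    truth = truth), class = "synth_dataset")
}
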