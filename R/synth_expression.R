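# Synthetic 29-tissue FPKM matrix and differential-expression table with
# planted seed-specific, candidate and decoy genes.

#' Tissue panel used by the synthetic expression matrix
#'
#' Seven seed developmental stages (S1-S7) from each of two cultivars (the
#' small-seeded Himchana 1 and the large-seeded JGK 3), plus 15 vegetative
#' and floral tissues.
#'
#' @return data.frame with `tissue`, `is_seed`, `stage` (S1-S7 or NA) and
#'   `cultivar` (NA for non-seed tissues).
#' @export
tissue_panel <- function() {
  stages <- paste0("S", 1:7)
  seed <- expand.grid(cultivar = c("Himchana1", "JGK3"), stage = stages,
                      stringsAsFactors = FALSE)
  seed <- seed[order(seed$cultivar, seed$stage), ]
  veg <- c("root", "stem", "leaf", "shoot_apex", "flower_bud", "flower",
           "young_pod", "nodule", "petal", "sepal", "anther", "pollen",
           "tendril", "seedling", "pedicel")
  data.frame(
    tissue = c(paste(seed$cultivar, seed$stage, sep = "_"), veg),
    is_seed = c(rep(TRUE, nrow(seed)), rep(FALSE, length(veg))),
    stage = c(seed$stage, rep(NA_character_, length(veg))),
    cultivar = c(seed$cultivar, rep(NA_character_, length(veg))),
    row.names = NULL)
}

#' Generate the expression matrix and DE table with planted truth
#'
#' Plants (i) candidate genes: seed-specific profiles peaking at S3/S5 of the
#' large-seeded cultivar with an emitted DE row passing the fold-change >= 2
#' and q <= 0.05 gate; (ii) seed-specific decoys whose DE rows fail the gate
#' (insufficient fold change, q too large, or higher in the small cultivar);
#' (iii) seed-specific genes without polymorphism evidence; and (iv)
#' background genes that are ubiquitous, expressed-except-seed, or silent.
#' Every planted seed-specific profile is verified at generation time to
#' classify as seed-specific (tau > 0.6, peak in a seed stage).
#'
#' @param cfg a [synth_config()].
#' @param genes list of gene models.
#' @param truth truth list from [plant_variants()].
#' @return list with `expression` (genes x 29 FPKM matrix), `tissue_meta`,
#'   `de_table` (gene_id, stage, log2fc, q; log2fc > 0 means higher in the
#'   large-seeded cultivar) and the augmented `truth`.
#' @export
generate_expression <- function(cfg, genes, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 3L)
  meta <- tissue_panel()
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  n <- length(gene_ids)
  nt <- nrow(meta)
  seed_cols <- which(meta$is_seed)
  large_s3s5 <- which(meta$tissue %in% c("JGK3_S3", "JGK3_S5"))

  ev <- truth$gene_evidence$gene_id
  ev <- resample(ev, length(ev))
  n_ss <- min(cfg$n_seed_specific, n)
  n_cand <- min(max(3L, round(n_ss * 0.3)), length(ev), n_ss)
  cand <- head(ev, n_cand)
  n_fail <- min(round(n_ss * 0.2), length(ev) - n_cand)
  ss_fail <- ev[seq_len(n_fail) + n_cand]
  remaining <- setdiff(gene_ids, c(cand, ss_fail))
  n_plain <- max(0L, n_ss - n_cand - n_fail)
  # prefer genes without polymorphism evidence as plain seed-specific decoys;
  # fill from evidence genes (which then simply lack a DE row) if needed
  pref <- setdiff(remaining, ev)
  ss_plain <- head(c(resample(pref, length(pref)),
                     resample(setdiff(remaining, pref),
                              length(setdiff(remaining, pref)))), n_plain)
  ss_all <- c(cand, ss_fail, ss_plain)
  bg <- setdiff(gene_ids, ss_all)
  bg_pattern <- resample(c("ubiquitous", "non_seed", "not_expressed"),
                         length(bg), replace = TRUE,
                         prob = c(0.62, 0.28, 0.10))

  expr <- matrix(0, n, nt, dimnames = list(gene_ids, meta$tissue))
  noise <- function(k) 2^rnorm(k, 0, cfg$expression_noise_sd)

  draw_ss <- function(peak_col) {
    prof <- runif(nt, 0, 1.2)
    prof[peak_col] <- runif(1, 40, 300)
    prof
  }
  draw_ubiq <- function() {
    base <- 2^rnorm(1, 4, 0.8)
    base * noise(nt)
  }
  draw_nonseed <- function() {
    prof <- numeric(nt)
    base <- 2^rnorm(1, 4, 0.8)
    prof[-seed_cols] <- base * noise(nt - length(seed_cols))
    prof[seed_cols] <- runif(length(seed_cols), 0, 0.5)
    prof
  }
  check_pattern <- function(prof, want) {
    p <- classify_pattern(prof, meta$is_seed)
    p == want
  }

  de_rows <- list()
  add_de <- function(gene_id, stage, log2fc, q) {
    de_rows[[length(de_rows) + 1L]] <<- list(gene_id = gene_id, stage = stage,
                                             log2fc = log2fc, q = q)
  }

  for (g in ss_all) {
    peak <- if (g %in% cand) resample(large_s3s5) else resample(seed_cols)
    for (try in 1:50) {
      prof <- draw_ss(peak)
      if (check_pattern(prof, "seed_specific")) break
    }
    if (g %in% cand) {
      lfc <- runif(1, 1.2, 3)
      stage <- meta$stage[peak]
      # mirror the fold change in the small cultivar's column at that stage
      small_col <- which(meta$tissue == paste0("Himchana1_", stage))
      prof[small_col] <- prof[peak] / 2^lfc
      if (!check_pattern(prof, "seed_specific")) prof[small_col] <- 0.5
      add_de(g, stage, lfc, runif(1, 0.001, 0.04))
      if (runif(1) < 0.4) {
        other <- setdiff(c("S3", "S5"), stage)
        add_de(g, other, runif(1, 1.2, 3), runif(1, 0.001, 0.04))
      }
    } else if (g %in% ss_fail) {
      mode <- resample(c("low_fc", "high_q", "higher_in_small"))
      for (stage in c("S3", "S5")) {
        switch(mode,
          low_fc = add_de(g, stage, runif(1, 0.1, 0.9),
                          runif(1, 0.001, 0.04)),
          high_q = add_de(g, stage, runif(1, 1.2, 3), runif(1, 0.06, 0.5)),
          higher_in_small = add_de(g, stage, -runif(1, 1.2, 3),
                                   runif(1, 0.001, 0.04)))
      }
    }
    expr[g, ] <- prof
  }

  for (i in seq_along(bg)) {
    g <- bg[i]
    want <- bg_pattern[i]
    if (want == "not_expressed") next
    for (try in 1:50) {
      prof <- if (want == "ubiquitous") draw_ubiq() else draw_nonseed()
      if (check_pattern(prof, want)) break
    }
    expr[g, ] <- prof
  }

  # uninformative DE rows for background genes at non-focal stages
  for (g in resample(bg, min(30L, length(bg)))) {
    add_de(g, resample(paste0("S", c(1, 2, 4, 6, 7))),
           rnorm(1, 0, 1.5), runif(1))
  }

  de <- as.data.frame(data.table::rbindlist(de_rows))
  de <- de[order(de$gene_id, de$stage), ]
  rownames(de) <- NULL
  expr <- round(expr, 3)

  truth$seed_specific_genes <- sort(ss_all)
  truth$de_genes_s3s5 <- sort(cand)
  truth$candidate_genes <- sort(cand)
  truth$pattern <- data.frame(
    gene_id = c(ss_all, bg),
    pattern = c(rep("seed_specific", length(ss_all)), bg_pattern))
  truth$pattern <- truth$pattern[order(truth$pattern$gene_id), ]
  rownames(truth$pattern) <- NULL

  list(expression = expr, tissue_meta = meta, de_table = de, truth = truth)
}
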