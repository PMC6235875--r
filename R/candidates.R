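# QTL containment, candidate-gene intersection and genotyping-platform
# concordance.

#' QTL membership of a gene
#'
#' A gene is "located within" a QTL when its span is fully contained in the
#' interval (0-based half-open coordinates). `mode = "overlap"` relaxes this
#' to any overlap.
#'
#' @param gene gene model (or any list with chrom, start, end).
#' @param qtls data.frame with chrom, start, end, name.
#' @param mode containment rule.
#' @return list with `member` (logical) and `qtls` (names of all containing
#'   intervals).
#' @export
qtl_membership <- function(gene, qtls, mode = c("within", "overlap")) {
  mode <- match.arg(mode)
  same <- qtls$chrom == gene$chrom
  hit <- if (mode == "within") {
    same & qtls$start <= gene$start & qtls$end >= gene$end
  } else {
    same & qtls$start < gene$end & qtls$end > gene$start
  }
  list(member = any(hit), qtls = qtls$name[hit])
}

#' Candidate genes for seed size/weight
#'
#' A candidate is a seed-specific gene (pattern `seed_specific`) that harbors
#' a promoter polymorphism and/or a non-synonymous or large-effect change,
#' and shows higher expression in the large-seeded cultivar at S3 and/or S5.
#' The three marginal lists (promoter / non-synonymous / large-effect) are
#' returned as well, since a gene can appear in more than one.
#'
#' @param spec data.frame from [specificity_screen()].
#' @param evidence data.frame with gene_id, has_promoter_poly, has_nonsyn,
#'   has_large_effect (e.g. from [gene_evidence()]).
#' @param de_flags named logical vector from [s3s5_higher_in_large()].
#' @param genes optional list of gene models (required for QTL membership).
#' @param qtls optional QTL data.frame.
#' @param categories optional data.frame with gene_id, category.
#' @param qtl_mode containment rule for QTL membership.
#' @return list with `candidates` (one row per candidate gene with evidence
#'   flags, QTL membership and category) and `marginal` (the three lists).
#' @export
select_candidates <- function(spec, evidence, de_flags, genes = NULL,
                              qtls = NULL, categories = NULL,
                              qtl_mode = "within") {
  if (!all(evidence$gene_id %in% spec$gene_id)) {
    stop("validation error: evidence gene ids not present in the ",
         "specificity results")
  }
  if (length(de_flags) && !all(names(de_flags) %in% spec$gene_id)) {
    stop("validation error: DE gene ids not present in the specificity ",
         "results")
  }
  ss <- spec$gene_id[spec$pattern == "seed_specific"]
  ev <- evidence[evidence$has_promoter_poly | evidence$has_nonsyn |
                   evidence$has_large_effect, , drop = FALSE]
  de_pass <- names(de_flags)[de_flags]
  cand_ids <- sort(intersect(intersect(ss, ev$gene_id), de_pass))

  make_tbl <- function(ids) {
    if (!length(ids)) {
      return(data.frame(gene_id = character(0),
                        has_promoter_poly = logical(0),
                        has_nonsyn = logical(0),
                        has_large_effect = logical(0),
                        de_s3s5_higher_in_large = logical(0),
                        qtl_member = logical(0), qtl_names = character(0),
                        category = character(0)))
    }
    m <- match(ids, evidence$gene_id)
    out <- data.frame(gene_id = ids,
                      has_promoter_poly = evidence$has_promoter_poly[m],
                      has_nonsyn = evidence$has_nonsyn[m],
                      has_large_effect = evidence$has_large_effect[m],
                      de_s3s5_higher_in_large = unname(de_flags[ids]))
    if (!is.null(genes) && !is.null(qtls)) {
      gid <- vapply(genes, `[[`, character(1), "gene_id")
      mem <- lapply(ids, function(g) {
        qtl_membership(genes[[match(g, gid)]], qtls, qtl_mode)
      })
      out$qtl_member <- vapply(mem, `[[`, logical(1), "member")
      out$qtl_names <- vapply(mem, function(x) {
        paste(x$qtls, collapse = ",")
      }, character(1))
    } else {
      out$qtl_member <- NA
      out$qtl_names <- NA_character_
    }
    out$category <- if (!is.null(categories)) {
      cm <- match(ids, categories$gene_id)
      ifelse(is.na(cm), "unassigned", categories$category[cm])
    } else "unassigned"
    out
  }

  cand <- make_tbl(cand_ids)
  list(candidates = cand,
       marginal = list(
         promoter = cand$gene_id[cand$has_promoter_poly],
         non_synonymous = cand$gene_id[cand$has_nonsyn],
         large_effect = cand$gene_id[cand$has_large_effect]))
}

#' Per-gene polymorphism evidence flags from annotated variants
#'
#' @param annotated data.frame from [annotate_variants()].
#' @return data.frame with gene_id, has_promoter_poly, has_nonsyn,
#'   has_large_effect for every gene with at least one qualifying variant.
#' @export
gene_evidence <- function(annotated) {
  a <- annotated[!is.na(annotated$gene_id), , drop = FALSE]
  qual <- a$region == "promoter" |
    a$consequence %in% c("non_synonymous", "large_effect")
  ids <- sort(unique(a$gene_id[qual]))
  data.frame(
    gene_id = ids,
    has_promoter_poly = vapply(ids, function(g) {
      any(a$gene_id == g & a$region == "promoter")
    }, logical(1)),
    has_nonsyn = vapply(ids, function(g) {
      any(a$gene_id == g & a$consequence == "non_synonymous")
    }, logical(1)),
    has_large_effect = vapply(ids, function(g) {
      any(a$gene_id == g & a$consequence == "large_effect")
    }, logical(1)),
    row.names = NULL)
}

#' Genotype concordance between two platforms
#'
#' Compares base calls over identical site x cultivar grids (e.g. genome
#' resequencing versus mass-spectrometry genotyping of validation SNPs) and
#' reports the fraction of matching cells.
#'
#' @param set_a,set_b data.frames with `site`, `cultivar`, `base`.
#' @return list with n_sites, n_cultivars, n_comparisons, n_matches and
#'   concordance.
#' @export
genotype_concordance <- function(set_a, set_b) {
  if (!nrow(set_a) || !nrow(set_b)) {
    stop("insufficient data: zero comparisons")
  }
  key <- function(d) paste(d$site, d$cultivar, sep = "|")
  ka <- key(set_a); kb <- key(set_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("validation error: duplicated site/cultivar cells")
  }
  if (!setequal(ka, kb)) {
    stop("validation error: site/cultivar keys differ between the sets")
  }
  n_sites <- length(unique(set_a$site))
  n_cult <- length(unique(set_a$cultivar))
  if (nrow(set_a) != n_sites * n_cult) {
    stop("validation error: incomplete site x cultivar grid")
  }
  b <- set_b$base[match(ka, kb)]
  n_match <- sum(set_a$base == b)
  list(n_sites = n_sites, n_cultivars = n_cult,
       n_comparisons = nrow(set_a), n_matches = n_match,
       concordance = n_match / nrow(set_a))
}
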