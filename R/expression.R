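# Tissue-specificity index, expression-pattern classification, the
# seed-specific screen and the differential-expression gate.

#' Tissue-specificity index (tau)
#'
#' tau = sum(1 - x_hat) / (N - 1), where x_hat is the profile normalized by
#' its maximum. By default values are log2(x + 1)-transformed first. tau is 0
#' for a uniform profile and 1 for single-tissue expression.
#'
#' @param profile non-negative FPKM vector over at least two tissues, not all
#'   zero.
#' @param log_transform apply log2(x + 1) before normalizing (default TRUE).
#' @return list with `tau` and `peak` (index of the maximum; ties broken by
#'   tissue order).
#' @export
tau_index <- function(profile, log_transform = TRUE) {
  if (length(profile) < 2L) stop("validation error: need at least 2 tissues")
  if (any(profile < 0)) stop("validation error: negative expression values")
  if (all(profile == 0)) {
    stop("not expressed: all-zero profile has no specificity index")
  }
  x <- if (log_transform) log2(profile + 1) else profile
  xhat <- x / max(x)
  list(tau = sum(1 - xhat) / (length(x) - 1L), peak = which.max(x))
}

#' Classify a gene's expression pattern
#'
#' `not_expressed` when every tissue is below `expressed_cutoff_fpkm`;
#' `seed_specific` when the peak tissue is a seed stage and tau strictly
#' exceeds `tau_threshold`; `non_seed` when expressed in at least one
#' non-seed tissue but below the cutoff in every seed stage; otherwise
#' `ubiquitous`.
#'
#' @param profile FPKM vector.
#' @param is_seed logical vector flagging seed-stage tissues.
#' @param expressed_cutoff_fpkm expression floor (default 1 FPKM).
#' @param tau_threshold seed-specificity threshold (default 0.6, strict).
#' @param log_transform passed to [tau_index()].
#' @return one of "not_expressed", "seed_specific", "non_seed", "ubiquitous".
#' @export
classify_pattern <- function(profile, is_seed, expressed_cutoff_fpkm = 1,
                             tau_threshold = 0.6, log_transform = TRUE) {
  if (length(is_seed) != length(profile) || anyNA(is_seed)) {
    stop("validation error: is_seed flags must match the profile")
  }
  if (all(profile < expressed_cutoff_fpkm)) return("not_expressed")
  ti <- tau_index(profile, log_transform)
  if (is_seed[ti$peak] && ti$tau > tau_threshold) return("seed_specific")
  if (any(profile[!is_seed] >= expressed_cutoff_fpkm) &&
      all(profile[is_seed] < expressed_cutoff_fpkm)) {
    return("non_seed")
  }
  "ubiquitous"
}

#' Seed-specific screen over an expression matrix
#'
#' @param expr genes x tissues FPKM matrix.
#' @param tissue_meta data.frame with `tissue` and `is_seed` matching the
#'   matrix columns.
#' @param ... passed to [classify_pattern()].
#' @return data.frame with gene_id, tau (NA when not expressed), peak_tissue
#'   and pattern.
#' @export
specificity_screen <- function(expr, tissue_meta, ...) {
  stopifnot(identical(colnames(expr), tissue_meta$tissue))
  res <- lapply(rownames(expr), function(g) {
    prof <- expr[g, ]
    pat <- classify_pattern(prof, tissue_meta$is_seed, ...)
    if (pat == "not_expressed") {
      data.frame(gene_id = g, tau = NA_real_, peak_tissue = NA_character_,
                 pattern = pat)
    } else {
      ti <- tau_index(prof)
      data.frame(gene_id = g, tau = ti$tau,
                 peak_tissue = tissue_meta$tissue[ti$peak], pattern = pat)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Differential-expression gate
#'
#' Passes when |log2 fold change| >= log2(`min_fold`) and q <= `max_q`
#' (defaults: fold change of at least two, corrected q-value of at most
#' 0.05). Direction comes from the sign of the fold change (positive = higher
#' in the large-seeded cultivar).
#'
#' @param log2fc numeric vector of log2 fold changes (large vs small).
#' @param q corrected q-values.
#' @param min_fold minimum fold change (default 2).
#' @param max_q maximum q-value (default 0.05).
#' @return data.frame with `pass` and `higher_in` ("large"/"small").
#' @export
de_gate <- function(log2fc, q, min_fold = 2, max_q = 0.05) {
  data.frame(pass = abs(log2fc) >= log2(min_fold) & q <= max_q,
             higher_in = ifelse(log2fc > 0, "large", "small"))
}

#' Higher expression in the large-seeded cultivar at S3 and/or S5
#'
#' @param de data.frame with gene_id, stage, log2fc, q.
#' @param min_fold,max_q gate parameters (see [de_gate()]).
#' @return named logical vector over the genes present in `de`: TRUE iff the
#'   gate passes with direction "large" at stage S3 or S5.
#' @export
s3s5_higher_in_large <- function(de, min_fold = 2, max_q = 0.05) {
  gate <- de_gate(de$log2fc, de$q, min_fold, max_q)
  hit <- gate$pass & gate$higher_in == "large" & de$stage %in% c("S3", "S5")
  vapply(split(hit, de$gene_id), any, logical(1))
}

#' Fold change and q-values from replicate FPKMs
#'
#' A stand-in for an upstream differential-expression caller, used for
#' synthetic tests when no DE table is supplied: fold change from replicate
#' means with a pseudocount of 1, q-values by Benjamini-Hochberg over
#' per-gene two-sample t statistics.
#'
#' @param large,small genes x replicates FPKM matrices (same rownames).
#' @param stage stage label attached to the output.
#' @return data.frame with gene_id, stage, log2fc, q.
#' @export
de_from_replicates <- function(large, small, stage = "S3") {
  stopifnot(identical(rownames(large), rownames(small)))
  lfc <- log2((rowMeans(large) + 1) / (rowMeans(small) + 1))
  p <- vapply(seq_len(nrow(large)), function(i) {
    if (stats::sd(c(large[i, ], small[i, ])) == 0) return(1)
    tryCatch(t.test(large[i, ], small[i, ])$p.value, error = function(e) 1)
  }, numeric(1))
  data.frame(gene_id = rownames(large), stage = stage, log2fc = lfc,
             q = p.adjust(p, method = "BH"))
}
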