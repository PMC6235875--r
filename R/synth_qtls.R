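#' Generate QTL intervals over the synthetic genes
#'
#' Emits intervals that fully contain a configured subset of genes; roughly a
#' third of the intervals additionally end inside a neighbouring gene, which
#' is therefore not a member under the containment rule. Stands in for
#' seed-size/weight QTL coordinates taken from linkage studies.
#'
#' @param cfg a [synth_config()].
#' @param genes list of gene models.
#' @param focus_genes optional gene ids to prefer as QTL anchors (e.g. planted
#'   candidate genes).
#' @return list with `qtls` (data.frame: chrom, start, end, name; 0-based
#'   half-open) and `members` (data.frame: name, gene_id of fully contained
#'   genes).
#' @export
generate_qtls <- function(cfg, genes, focus_genes = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 4L)
  if (cfg$n_qtls == 0L || !length(genes)) {
    return(list(qtls = data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0), name = character(0)),
                members = data.frame(name = character(0),
                                     gene_id = character(0))))
  }
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  spans <- data.frame(
    gene_id = gene_ids,
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = vapply(genes, function(g) g$start, numeric(1)),
    end = vapply(genes, function(g) g$end, numeric(1)))
  spans <- spans[order(spans$chrom, spans$start), ]

  n_focus <- min(length(focus_genes), ceiling(cfg$n_qtls / 2))
  anchors <- character(0)
  if (n_focus > 0) anchors <- resample(focus_genes, n_focus)
  pool <- setdiff(gene_ids, anchors)
  extra <- min(cfg$n_qtls - length(anchors), length(pool))
  anchors <- c(anchors, resample(pool, extra))

  qtl_rows <- list()
  member_rows <- list()
  for (k in seq_along(anchors)) {
    g <- spans[spans$gene_id == anchors[k], ]
    idx <- which(spans$chrom == g$chrom)
    pos_in <- which(spans$gene_id[idx] == g$gene_id)
    lo <- g$start - sample(200:1500, 1L)
    hi <- g$end + sample(200:1500, 1L)
    # sometimes stretch over following genes (contained)
    if (runif(1) < 0.5 && pos_in < length(idx)) {
      nxt <- spans[idx[pos_in + 1L], ]
      if (runif(1) < 0.6) {
        hi <- nxt$end + sample(200:1500, 1L)     # neighbour fully contained
      } else {
        hi <- nxt$start + max(50L,
          floor((nxt$end - nxt$start) / 2))      # neighbour cut in half
      }
    }
    name <- sprintf("qtl%02d", k)
    qtl_rows[[k]] <- list(chrom = g$chrom, start = max(0L, as.integer(lo)),
                          end = as.integer(hi), name = name)
    inside <- spans$chrom == g$chrom & spans$start >= lo & spans$end <= hi
    for (m in spans$gene_id[inside]) {
      member_rows[[length(member_rows) + 1L]] <- list(name = name,
                                                      gene_id = m)
    }
  }
  qtls <- as.data.frame(data.table::rbindlist(qtl_rows))
  members <- if (length(member_rows)) {
    as.data.frame(data.table::rbindlist(member_rows))
  } else {
    data.frame(name = character(0), gene_id = character(0))
  }
  list(qtls = qtls, members = members)
}
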