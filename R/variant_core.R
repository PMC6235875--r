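# Variant classification, site filters, the 10-bp clustering density filter,
# and the group-differential computation between the small- and large-seeded
# cultivar pairs.

#' Classify a variant into SNP / MNP / InDel / complex
#'
#' Alleles are first reduced to their minimal representation (shared suffix
#' then prefix stripped). A SNP substitutes one base; an MNP substitutes two
#' or more consecutive bases with no length change; an InDel is a pure length
#' change (one allele is a prefix/suffix extension of the other); everything
#' else (substitution mixed with length change) is complex.
#'
#' @param ref,alt allele strings (non-empty, unequal).
#' @return one of "SNP", "MNP", "InDel", "complex".
#' @export
classify_variant <- function(ref, alt) {
  tr <- trim_alleles(ref, alt)
  nr <- nchar(tr$ref); na <- nchar(tr$alt)
  if (nr == 0L || na == 0L) return("InDel")
  if (nr == 1L && na == 1L) return("SNP")
  if (nr == na) return("MNP")
  "complex"
}

#' Vectorized [classify_variant()]
#' @param ref,alt character vectors of alleles.
#' @return character vector of classes.
#' @export
classify_variants <- function(ref, alt) {
  mapply(classify_variant, ref, alt, USE.NAMES = FALSE)
}

#' Filter variant calls on read depth and alternate-allele fraction
#'
#' Retains calls with depth >= `min_depth` and alternate fraction >=
#' `min_alt_fraction` (defaults match the calling parameters min-coverage 10,
#' min-alternate-fraction 0.9). Order is preserved.
#'
#' @param calls data.frame with `depth` and `alt_fraction` columns.
#' @param min_depth minimum read depth.
#' @param min_alt_fraction minimum alternate-allele fraction.
#' @return the retained rows of `calls`.
#' @export
filter_calls <- function(calls, min_depth = 10, min_alt_fraction = 0.9) {
  if (min_depth <= 0) stop("min_depth must be positive")
  if (min_alt_fraction < 0 || min_alt_fraction > 1) {
    stop("min_alt_fraction must be in [0, 1]")
  }
  if (!nrow(calls)) return(calls)
  keep <- calls$depth >= min_depth & calls$alt_fraction >= min_alt_fraction
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# logical flag: TRUE where a position lies in a 10-bp window (any alignment)
# holding more than max_in_window variants. Equivalently, a position is
# removed iff it belongs to a run of (max_in_window + 1) variants whose
# start-position span is <= window_bp - 1.
density_removed_flags <- function(positions, window_bp = 10L,
                                  max_in_window = 2L) {
  n <- length(positions)
  k <- max_in_window + 1L
  removed <- logical(n)
  if (is.unsorted(positions)) {
    stop("validation error: positions must be sorted")
  }
  if (n < k) return(removed)
  span <- positions[k:n] - positions[1:(n - k + 1L)]
  bad <- which(span <= window_bp - 1L)
  for (i in bad) removed[i:(i + k - 1L)] <- TRUE
  removed
}

#' Remove variants clustered within a short window
#'
#' A variant is removed iff it lies in at least one `window_bp` window (any
#' alignment) containing more than `max_in_window` variant start positions —
#' the defaults implement removal of polymorphisms when three or more fall
#' within any 10-bp window.
#'
#' @param positions sorted integer vector of variant start positions on one
#'   chromosome.
#' @param window_bp window width in bp.
#' @param max_in_window maximum number of variants tolerated per window.
#' @return the retained positions.
#' @export
density_filter <- function(positions, window_bp = 10L, max_in_window = 2L) {
  positions[!density_removed_flags(positions, window_bp, max_in_window)]
}

# internal: assemble per-site per-cultivar allele table
# calls: all cultivars' calls; coverage: chrom/pos/cultivar/depth (0-based)
site_alleles <- function(calls, coverage, cultivars, min_depth,
                         min_alt_fraction) {
  bad_cult <- setdiff(unique(calls$cultivar), cultivars)
  if (length(bad_cult)) {
    stop("validation error: unknown cultivar id ", bad_cult[1])
  }
  good <- filter_calls(calls, min_depth, min_alt_fraction)
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  sites <- unique(calls[, c("chrom", "pos", "ref")])
  if (anyDuplicated(key(sites))) {
    dup <- key(sites)[duplicated(key(sites))][1]
    stop("validation error: conflicting REF alleles at site ", dup)
  }
  sites <- sites[order(sites$chrom, sites$pos), ]
  rownames(sites) <- NULL
  skey <- key(sites)

  al <- matrix(NA_character_, nrow(sites), length(cultivars),
               dimnames = list(NULL, cultivars))
  # reference where covered
  if (!is.null(coverage) && nrow(coverage)) {
    cov_ok <- coverage[coverage$depth >= min_depth, ]
    for (cu in cultivars) {
      cc <- cov_ok[cov_ok$cultivar == cu, ]
      hit <- skey %in% key(cc)
      al[hit, cu] <- sites$ref[hit]
    }
  }
  # no-call where a record exists but failed the filters
  for (cu in cultivars) {
    cc <- calls[calls$cultivar == cu, ]
    gg <- good[good$cultivar == cu, ]
    failed <- setdiff(key(cc), key(gg))
    al[skey %in% failed, cu] <- NA_character_
    # confident alternate calls
    idx <- match(key(gg), skey)
    al[idx[!is.na(idx)], cu] <- gg$alt[!is.na(idx)]
  }
  list(sites = sites, alleles = al, good = good)
}

#' Variants differentiating the small- and large-seeded cultivar groups
#'
#' A site is emitted iff (i) all four cultivars have a confident call —
#' either a variant call passing the depth/alternate-fraction filters or a
#' reference call backed by coverage of at least `min_depth`; (ii) the two
#' small-seeded cultivars carry identical alleles; (iii) the two large-seeded
#' cultivars carry identical alleles; and (iv) the two group alleles differ.
#' Variants clustered within `density_window` bp (more than `density_max` per
#' window) are removed from the merged per-chromosome call set before the
#' group comparison.
#'
#' @param calls data.frame of per-cultivar calls (chrom, pos, ref, alt,
#'   cultivar, depth, alt_fraction; 0-based positions).
#' @param coverage data.frame (chrom, pos, cultivar, depth) giving per-site
#'   read depth, used to accept reference alleles; `NULL` treats missing
#'   records as no-calls.
#' @param small,large character vectors of cultivar ids in each group.
#' @param min_depth,min_alt_fraction site filters (defaults 10 and 0.9).
#' @param density_window,density_max density-filter parameters (10 bp, max 2).
#' @param apply_density set `FALSE` to skip the density filter.
#' @return data.frame with chrom, pos, ref, small_allele, large_allele,
#'   alt (the substituted allele: the large-group allele when it differs from
#'   the reference, otherwise the small-group allele) and class.
#' @export
group_differential <- function(calls, coverage, small, large,
                               min_depth = 10, min_alt_fraction = 0.9,
                               density_window = 10L, density_max = 2L,
                               apply_density = TRUE) {
  if (!length(small) || !length(large)) {
    stop("validation error: both groups need at least one cultivar")
  }
  if (length(intersect(small, large))) {
    stop("validation error: groups overlap")
  }
  cultivars <- c(small, large)
  sa <- site_alleles(calls, coverage, cultivars, min_depth, min_alt_fraction)
  sites <- sa$sites; al <- sa$alleles

  keep <- rep(TRUE, nrow(sites))
  if (apply_density && nrow(sa$good)) {
    merged <- unique(sa$good[, c("chrom", "pos")])
    merged <- merged[order(merged$chrom, merged$pos), ]
    removed_key <- character(0)
    for (ch in unique(merged$chrom)) {
      p <- merged$pos[merged$chrom == ch]
      flag <- density_removed_flags(p, density_window, density_max)
      removed_key <- c(removed_key, paste(ch, p[flag], sep = ":"))
    }
    keep <- !(paste(sites$chrom, sites$pos, sep = ":") %in% removed_key)
  }

  confident <- rowSums(is.na(al)) == 0L
  s1 <- al[, small[1]]
  small_same <- Reduce(`&`, lapply(small, function(cu) al[, cu] == s1))
  l1 <- al[, large[1]]
  large_same <- Reduce(`&`, lapply(large, function(cu) al[, cu] == l1))
  differ <- s1 != l1
  sel <- which(keep & confident & small_same & large_same & differ)
  if (!length(sel)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), small_allele = character(0),
                      large_allele = character(0), alt = character(0),
                      class = character(0)))
  }
  out <- sites[sel, ]
  out$small_allele <- s1[sel]
  out$large_allele <- l1[sel]
  out$alt <- ifelse(out$large_allele != out$ref, out$large_allele,
                    out$small_allele)
  out$class <- classify_variants(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' One-to-one differential variants between two cultivars
#'
#' [group_differential()] restricted to two single-cultivar groups. The
#' group-differentiating set is always a subset of every small-versus-large
#' pairwise set computed with the same filters.
#'
#' @param calls,coverage as in [group_differential()].
#' @param cultivar_a,cultivar_b the two cultivar ids.
#' @param ... further arguments passed to [group_differential()].
#' @return data.frame as in [group_differential()], where `small_allele`
#'   belongs to `cultivar_a` and `large_allele` to `cultivar_b`.
#' @export
pairwise_differential <- function(calls, coverage, cultivar_a, cultivar_b,
                                  ...) {
  if (identical(cultivar_a, cultivar_b)) {
    stop("validation error: cultivars must differ")
  }
  sub <- calls[calls$cultivar %in% c(cultivar_a, cultivar_b), , drop = FALSE]
  cov <- if (is.null(coverage)) NULL else
    coverage[coverage$cultivar %in% c(cultivar_a, cultivar_b), , drop = FALSE]
  group_differential(sub, cov, small = cultivar_a, large = cultivar_b, ...)
}
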