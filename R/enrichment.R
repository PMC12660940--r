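#' MAF / TSS-distance matching bins
#'
#' Bin edges used to match null SNPs to sentinels: MAF edges 0.01, 0.05,
#' 0.1, 0.2, 0.3, 0.5 and TSS-distance edges 0, 1 kb, 10 kb, 100 kb, 1 Mb.
#' Cells are half-open (lower, upper] with the lowest edge inclusive.
#'
#' @param maf_edges,tss_dist_edges strictly increasing edge vectors.
#' @return a \code{match_bins} list.
#' @export
match_bins <- function(maf_edges = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5),
                       tss_dist_edges = c(0, 1e3, 1e4, 1e5, 1e6)) {
  stopifnot(all(diff(maf_edges) > 0), all(diff(tss_dist_edges) > 0))
  structure(list(maf_edges = maf_edges, tss_dist_edges = tss_dist_edges),
            class = "match_bins")
}

#' Assign a SNP to a matching cell
#'
#' @param maf folded MAF (must lie within the MAF grid, i.e. >= lowest
#'   edge as the pool is pre-filtered to MAF >= 0.01).
#' @param tss_dist distance to the TSS in bp.
#' @param bins a [match_bins()] object.
#' @return integer vector of cell ids (1-based, row-major over
#'   maf x distance cells); vectorized.
#' @export
assign_bin <- function(maf, tss_dist, bins = match_bins()) {
  me <- bins$maf_edges
  de <- bins$tss_dist_edges
  if (any(maf < me[1L] | maf > me[length(me)])) {
    stop("MAF outside the matching grid [", me[1L], ", ", me[length(me)], "]")
  }
  if (any(tss_dist < de[1L] | tss_dist > de[length(de)])) {
    stop("TSS distance outside the matching grid [", de[1L], ", ",
         de[length(de)], "]")
  }
  mi <- findInterval(maf, me, left.open = TRUE)   # (lower, upper]
  mi[maf == me[1L]] <- 1L                          # lowest edge inclusive
  di <- findInterval(tss_dist, de, left.open = TRUE)
  di[tss_dist == de[1L]] <- 1L
  (mi - 1L) * (length(de) - 1L) + di
}

#' Describe a matching cell id
#' @param cell integer cell id from [assign_bin()].
#' @param bins the [match_bins()] used.
#' @return character label "maf(lo,hi]xdist(lo,hi]".
#' @export
bin_label <- function(cell, bins = match_bins()) {
  nd <- length(bins$tss_dist_edges) - 1L
  mi <- (cell - 1L) %/% nd + 1L
  di <- (cell - 1L) %% nd + 1L
  sprintf("maf(%g,%g] x dist(%g,%g]",
          bins$maf_edges[mi], bins$maf_edges[mi + 1L],
          bins$tss_dist_edges[di], bins$tss_dist_edges[di + 1L])
}

#' Sample matched null SNP sets
#'
#' Draws \code{n_sets} null sets, each containing one pool SNP per
#' sentinel sampled uniformly (with replacement across sets) from the
#' sentinel's (MAF, TSS-distance) cell. Sentinel SNPs themselves are
#' removed from the pool. An empty cell is an error (no silent fallback).
#'
#' @param sentinels data.table with snp, maf, tss_dist.
#' @param pool data.table with snp, maf, tss_dist (pre-filtered to
#'   MAF >= 0.01 and HWE-passing variants).
#' @param n_sets number of null sets (default 1000).
#' @param bins a [match_bins()].
#' @param seed RNG seed.
#' @return character matrix n_sentinels x n_sets of null SNP ids.
#' @export
sample_matched_nulls <- function(sentinels, pool, n_sets = 1000L,
                                 bins = match_bins(), seed = 1L) {
  set.seed(seed)
  pool <- pool[!snp %in% sentinels$snp]
  s_cell <- assign_bin(sentinels$maf, pmin(sentinels$tss_dist,
                                           max(bins$tss_dist_edges)), bins)
  p_cell <- assign_bin(pool$maf, pmin(pool$tss_dist,
                                      max(bins$tss_dist_edges)), bins)
  by_cell <- split(pool$snp, p_cell)
  out <- matrix(NA_character_, nrow(sentinels), n_sets)
  for (cell in unique(s_cell)) {
    rows <- which(s_cell == cell)
    cand <- by_cell[[as.character(cell)]]
    if (is.null(cand) || !length(cand)) {
      stop("no pool SNPs in cell ", bin_label(cell, bins), " (",
           length(rows), " sentinel(s))")
    }
    out[rows, ] <- sample(cand, length(rows) * n_sets, replace = TRUE)
  }
  rownames(out) <- sentinels$snp
  out
}

#' Matched-null fold enrichment in a genomic feature
#'
#' Fold enrichment is the observed proportion of sentinels overlapping the
#' feature divided by the mean proportion across the matched null sets.
#' Per-set folds (observed / null-set proportion) are retained for
#' distribution comparisons.
#'
#' @param sentinel_snps character vector of sentinel SNP ids.
#' @param null_sets matrix from [sample_matched_nulls()].
#' @param overlap named logical vector: feature overlap per SNP id (from
#'   [feature_overlap()] over the variant table).
#' @param feature feature name for the report.
#' @return list: feature, observed_proportion, null_proportions, fold,
#'   fold_distribution.
#' @export
fold_enrichment <- function(sentinel_snps, null_sets, overlap,
                            feature = "feature") {
  obs <- mean(overlap[sentinel_snps])
  nullp <- colMeans(matrix(overlap[null_sets], nrow(null_sets)))
  mnull <- mean(nullp)
  fold <- if (mnull > 0) obs / mnull else if (obs > 0) {
    warning("mean null proportion is zero; fold reported as Inf")
    Inf
  } else NA_real_
  folds <- ifelse(nullp > 0, obs / nullp, ifelse(obs > 0, Inf, NA_real_))
  list(feature = feature, observed_proportion = obs,
       null_proportions = nullp, fold = fold, fold_distribution = folds)
}

#' Compare two fold-enrichment distributions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test: exact enumeration when
#' both groups have at most 12 untied values, otherwise the normal
#' approximation with tie correction. All values tied across both groups
#' gives p = 1.
#'
#' @param folds_a,folds_b numeric fold distributions.
#' @return list: W, p, direction ("a>b"/"a<b"/"none").
#' @export
compare_fold_distributions <- function(folds_a, folds_b) {
  # per-set folds are NA where both proportions were zero; those sets carry
  # no ordering information
  folds_a <- folds_a[!is.na(folds_a)]
  folds_b <- folds_b[!is.na(folds_b)]
  if (!length(folds_a) || !length(folds_b)) stop("empty fold distribution")
  if (length(unique(c(folds_a, folds_b))) == 1L) {
    return(list(W = length(folds_a) * length(folds_b) / 2, p = 1,
                direction = "none"))
  }
  exact <- length(folds_a) <= 12L && length(folds_b) <= 12L &&
    !anyDuplicated(c(folds_a, folds_b))
  wt <- suppressWarnings(stats::wilcox.test(folds_a, folds_b,
                                            exact = exact, correct = FALSE))
  dir <- if (stats::median(folds_a) > stats::median(folds_b)) "a>b"
         else if (stats::median(folds_a) < stats::median(folds_b)) "a<b"
         else "none"
  list(W = unname(wt$statistic), p = wt$p.value, direction = dir)
}

#' Filter a trait-association catalog
#'
#' Keeps records with p < 5e-8 and either both discovery and replication
#' sample sizes >= 5000 or discovery sample size >= 10,000. Records with
#' missing p are dropped (count reported via message).
#'
#' @param catalog data.table with p, n_discovery, n_replication (missing
#'   replication size allowed).
#' @param p_max significance threshold (default 5e-8).
#' @return the filtered catalog.
#' @export
filter_catalog <- function(catalog, p_max = 5e-8) {
  miss <- sum(is.na(catalog$p))
  if (miss) message(miss, " catalog record(s) dropped for missing p")
  cat2 <- catalog[!is.na(p)]
  nd <- cat2$n_discovery
  nr <- cat2$n_replication
  size_ok <- (!is.na(nd) & !is.na(nr) & nd >= 5000 & nr >= 5000) |
    (!is.na(nd) & nd >= 10000)
  cat2[p < p_max & size_ok]
}

#' Fisher's exact enrichment of a QTL set in a catalog set
#'
#' Builds the 2x2 table (QTL-and-catalog, catalog-only, QTL-only,
#' neither) over the SNP universe and applies the two-sided Fisher exact
#' test; the reported odds ratio is the sample odds ratio ad/bc.
#'
#' @param qtl_set,catalog_set,universe character vectors of SNP ids;
#'   both sets must be subsets of the universe.
#' @return list: odds_ratio, p, table (2x2 matrix), significant (at the
#'   1e-4 reporting level).
#' @export
fisher_enrichment <- function(qtl_set, catalog_set, universe) {
  qtl_set <- unique(qtl_set)
  catalog_set <- unique(catalog_set)
  universe <- unique(universe)
  if (!all(qtl_set %in% universe) || !all(catalog_set %in% universe)) {
    stop("qtl_set and catalog_set must be subsets of the universe")
  }
  a <- sum(qtl_set %in% catalog_set)
  b <- length(catalog_set) - a
  cc <- length(qtl_set) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2L, 2L,
                dimnames = list(c("catalog", "no_catalog"),
                                c("qtl", "no_qtl")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- if (b > 0 && cc > 0) a * d / (b * cc) else Inf
  if (a == 0) or <- 0
  list(odds_ratio = or, p = ft$p.value, table = tab,
       significant = ft$p.value < 1e-4)
}

#' Distance to the nearest transcript TSS
#'
#' Matching distance for pool SNPs: the bp distance from each variant to
#' the nearest TSS in the annotation (on the same chromosome; variants on
#' chromosomes without any TSS get NA).
#'
#' @param variants variant table (chrom, pos).
#' @param annotation transcript annotation (chrom, tss).
#' @return numeric vector of distances.
#' @export
nearest_tss_distance <- function(variants, annotation) {
  out <- rep(NA_real_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    tss <- sort(unique(annotation[chrom == ch, tss]))
    if (!length(tss)) next
    i <- which(variants$chrom == ch)
    p <- variants$pos[i]
    j <- findInterval(p, tss)
    lo <- ifelse(j >= 1L, tss[pmax(j, 1L)], NA)
    hi <- ifelse(j < length(tss), tss[pmin(j + 1L, length(tss))], NA)
    out[i] <- pmin(abs(p - lo), abs(hi - p), na.rm = TRUE)
  }
  out
}
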