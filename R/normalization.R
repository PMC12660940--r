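#' Expression matrix container
#'
#' A transcripts x samples numeric matrix with a unit tag ("counts", "FPKM"
#' or "TMM") so downstream operations can assert they are fed the right
#' scale.
#'
#' @param values transcripts x samples numeric matrix (non-negative).
#' @param unit one of "counts", "FPKM", "TMM".
#' @return an \code{expr_matrix} object.
#' @export
expr_matrix <- function(values, unit = c("counts", "FPKM", "TMM")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), all(values >= 0 | is.na(values)))
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d transcripts x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Extract the value matrix of an expr_matrix
#' @param x an \code{expr_matrix} (a bare matrix passes through).
#' @return the numeric matrix.
#' @export
expr_values <- function(x) if (inherits(x, "expr_matrix")) x$values else x

#' Fragments per kilobase per million mapped reads
#'
#' \code{fpkm = count / (length_kb * library_size_millions)}.
#'
#' @param counts \code{expr_matrix} of counts (or bare matrix).
#' @param lengths per-transcript exonic length in bp (> 0), aligned to rows.
#' @param library_sizes per-sample mapped reads (> 0), aligned to columns.
#' @return \code{expr_matrix} with unit FPKM.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes) {
  m <- expr_values(counts)
  stopifnot(length(lengths) == nrow(m), length(library_sizes) == ncol(m))
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  zero <- which(library_sizes <= 0)
  if (length(zero)) {
    nm <- colnames(m)[zero[1L]] %||% as.character(zero[1L])
    stop("non-positive library size for sample ", nm)
  }
  f <- m / (lengths / 1e3)
  f <- sweep(f, 2L, library_sizes / 1e6, `/`)
  out <- expr_matrix(f, "FPKM")
  out
}

#' TMM scale factors (trimmed mean of M-values)
#'
#' Robinson-Oshlack TMM computed on the FPKM matrix via
#' \code{edgeR::calcNormFactors}: per-sample log2-ratios (M) and average
#' log2-intensities (A) against the reference sample are formed over
#' transcripts positive in both, doubly trimmed (\code{trim_m} on M,
#' \code{trim_a} on A), and the factor is 2 to the precision-weighted mean
#' M, rescaled so the factors' geometric mean is 1. Equal nominal library
#' sizes are supplied so the trimming acts on the FPKM values directly
#' (FPKM is already depth-normalized). The reference defaults to the sample
#' whose upper quartile is closest to the mean upper quartile.
#'
#' @param expr \code{expr_matrix} with unit FPKM (or bare matrix).
#' @param trim_m trim fraction on M values (default 0.30).
#' @param trim_a trim fraction on A values (default 0.05).
#' @param ref_sample optional reference sample name or index.
#' @return named per-sample scale-factor vector (geometric mean 1).
#' @export
compute_tmm_factors <- function(expr, trim_m = 0.30, trim_a = 0.05,
                                ref_sample = NULL) {
  m <- expr_values(expr)
  if (inherits(expr, "expr_matrix") && expr$unit != "FPKM") {
    stop("TMM factors are computed on the FPKM matrix, got unit ", expr$unit)
  }
  if (ncol(m) < 2L) stop("TMM needs at least two samples")
  allzero <- which(colSums(m) == 0)
  if (length(allzero)) {
    nm <- colnames(m)[allzero[1L]] %||% as.character(allzero[1L])
    stop("sample with all-zero expression: ", nm)
  }
  ref <- if (is.null(ref_sample)) NULL else {
    if (is.character(ref_sample)) match(ref_sample, colnames(m)) else ref_sample
  }
  f <- edgeR::calcNormFactors(m, lib.size = rep(1e6, ncol(m)),
                              method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a,
                              doWeighting = TRUE)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Apply TMM scale factors
#'
#' Divides each sample's values by its scale factor and tags the result TMM.
#'
#' @param expr FPKM \code{expr_matrix}.
#' @param factors factors from [compute_tmm_factors()] (names must match the
#'   sample set when both are named).
#' @return \code{expr_matrix} with unit TMM.
#' @export
apply_tmm <- function(expr, factors) {
  m <- expr_values(expr)
  if (length(factors) != ncol(m)) stop("mismatched sample sets")
  if (!is.null(names(factors)) && !is.null(colnames(m))) {
    if (!setequal(names(factors), colnames(m))) stop("mismatched sample sets")
    factors <- factors[colnames(m)]
  }
  expr_matrix(sweep(m, 2L, factors, `/`), "TMM")
}

#' Isoform ratios from TMM expression
#'
#' The ratio of an isoform in a sample is its TMM value divided by the sum
#' of TMM values over all isoforms of its parent gene in that sample; the
#' ratio is missing exactly where that gene sum is zero. Per gene and
#' sample, non-missing ratios sum to 1.
#'
#' @param expr TMM \code{expr_matrix} (rows named by transcript).
#' @param annotation transcript annotation (data.table from
#'   [read_annotation()] or [simulate_annotation()]).
#' @return an \code{isoform_ratios} object: list with \code{ratios}
#'   (transcripts x samples, NA where the gene total is zero),
#'   \code{annotation} rows aligned to the ratio rows, \code{missing_frac}
#'   and \code{median_tmm} per transcript.
#' @export
compute_isoform_ratios <- function(expr, annotation) {
  m <- expr_values(expr)
  if (inherits(expr, "expr_matrix") && expr$unit != "TMM") {
    stop("isoform ratios are computed on TMM values, got unit ", expr$unit)
  }
  idx <- match(rownames(m), annotation$transcript_id)
  if (anyNA(idx)) {
    stop("transcript without annotation: ", rownames(m)[which(is.na(idx))[1L]])
  }
  ann <- annotation[idx]
  gsum <- rowsum(m, ann$gene_id)
  denom <- gsum[match(ann$gene_id, rownames(gsum)), , drop = FALSE]
  ratios <- m / denom
  ratios[denom == 0] <- NA_real_
  structure(list(
    ratios = ratios,
    annotation = ann,
    missing_frac = rowMeans(is.na(ratios)),
    median_tmm = apply(m, 1L, stats::median)
  ), class = "isoform_ratios")
}

#' @export
print.isoform_ratios <- function(x, ...) {
  cat(sprintf("<isoform_ratios> %d transcripts (%d genes) x %d samples; %.1f%% missing\n",
              nrow(x$ratios), length(unique(x$annotation$gene_id)),
              ncol(x$ratios), 100 * mean(is.na(x$ratios))))
  invisible(x)
}

#' Transcript filters for the irQTL scan
#'
#' Keeps transcripts with population median TMM >= \code{median_min}
#' (boundary inclusive), missing fraction strictly below \code{max_missing},
#' and a parent gene carrying more than one annotated transcript before
#' filtering. The population median is taken over all samples including
#' zeros. A gene left with a single surviving transcript keeps it (its
#' ratio remains well defined).
#'
#' @param ratios \code{isoform_ratios} object.
#' @param median_min median TMM floor (default 2).
#' @param max_missing missing-fraction cap, strict (default 0.20).
#' @return filtered \code{isoform_ratios}; the filter report is attached as
#'   attribute \code{"report"} (transcript, median_tmm, missing_frac, kept).
#' @export
filter_transcripts <- function(ratios, median_min = 2, max_missing = 0.20) {
  stopifnot(inherits(ratios, "isoform_ratios"))
  ntx_gene <- table(ratios$annotation$gene_id)
  multi <- ntx_gene[ratios$annotation$gene_id] > 1L
  keep <- ratios$median_tmm >= median_min &
    ratios$missing_frac < max_missing & as.vector(multi)
  report <- data.table::data.table(
    transcript = rownames(ratios$ratios),
    median_tmm = ratios$median_tmm,
    missing_frac = ratios$missing_frac,
    multi_isoform = as.vector(multi),
    kept = keep)
  out <- structure(list(
    ratios = ratios$ratios[keep, , drop = FALSE],
    annotation = ratios$annotation[keep],
    missing_frac = ratios$missing_frac[keep],
    median_tmm = ratios$median_tmm[keep]
  ), class = "isoform_ratios")
  attr(out, "report") <- report
  out
}
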