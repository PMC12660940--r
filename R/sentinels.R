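#' LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of the dosages (composite-genotype r2) over
#' the overlapping non-missing samples.
#'
#' @param dosage_a,dosage_b dosage vectors of equal length.
#' @return r2 in [0, 1]; NA (with a warning) when either vector is constant
#'   on the overlap.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 3L) stop("fewer than 3 overlapping non-missing samples")
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("constant dosage vector; LD r2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Select sentinel cis-irQTLs
#'
#' Per isoform, the variant with the lowest p among its significant cis
#' records; every variant tying that minimum p whose LD r2 with it is 1
#' (within 1e-9) is also emitted, so an isoform can carry multiple
#' sentinels when they are in mutual perfect LD.
#'
#' @param records cis association records (from [scan_irqtl()]).
#' @param genotypes \code{genotype_data} for the LD check.
#' @param alpha significance level (default 5e-8).
#' @return data.table of sentinel pairs (snp, transcript, gene, chrom, pos,
#'   beta, se, p, r2, n, relation, distance).
#' @export
select_cis_sentinels <- function(records, genotypes, alpha = 5e-8) {
  sig <- records[relation == "cis" & p < alpha]
  if (!nrow(sig)) return(sig)
  out <- sig[, {
    best <- which.min(p)
    tie <- which(p == p[best] & seq_len(.N) != best)
    keep <- best
    if (length(tie)) {
      r2s <- vapply(tie, function(i) {
        suppressWarnings(ld_r2(genotypes$dosage[, snp[best]],
                               genotypes$dosage[, snp[i]]))
      }, numeric(1))
      keep <- c(best, tie[!is.na(r2s) & r2s >= 1 - 1e-9])
    }
    .SD[keep]
  }, by = transcript]
  data.table::setcolorder(out, names(sig))
  out[]
}

#' Select sentinel trans-irQTLs
#'
#' Per isoform and SNP chromosome, the variant with the lowest p among
#' significant trans records. Equal-p ties are broken by smaller se, then
#' lexicographic snp id, and the tie is recorded in the
#' \code{"ties"} attribute.
#'
#' @param records trans association records.
#' @param alpha trans significance level; default takes the stored
#'   \code{significant} flag.
#' @return data.table of sentinel trans pairs.
#' @export
select_trans_sentinels <- function(records, alpha = NULL) {
  sig <- if (is.null(alpha)) records[relation == "trans" & significant == TRUE]
         else records[relation == "trans" & p < alpha]
  if (!nrow(sig)) return(sig)
  out <- sig[, .SD[order(p, se, snp)[1L]], by = .(transcript, chrom)]
  tie_tab <- sig[, .(n_at_min = sum(p == min(p)),
                     snps = paste(snp[p == min(p)], collapse = ",")),
                 by = .(transcript, chrom)][n_at_min > 1L]
  data.table::setcolorder(out, names(sig))
  attr(out, "ties") <- if (nrow(tie_tab)) tie_tab else NULL
  out[]
}

#' Evaluate replication of sentinel pairs
#'
#' A pair replicates when its p in the replication records is below
#' \code{p_thresh} and the effect direction matches discovery. Pairs absent
#' from the replication output get \code{replicated = NA} and are excluded
#' from the rate's denominator ("present in both" samples).
#'
#' @param discovery sentinel pairs (needs snp, transcript, beta, p).
#' @param replication_records replication-scan records (snp, transcript,
#'   beta, p).
#' @param p_thresh replication p threshold (default 1e-4).
#' @return list: \code{pairs} (discovery with beta_repl, p_repl,
#'   replicated), \code{n_discovery}, \code{n_present}, \code{n_replicated},
#'   \code{rate}.
#' @export
evaluate_replication <- function(discovery, replication_records,
                                 p_thresh = 1e-4) {
  pairs <- data.table::copy(discovery)
  rep_sub <- replication_records[, .(snp, transcript, beta_repl = beta,
                                     p_repl = p)]
  pairs <- merge(pairs, rep_sub, by = c("snp", "transcript"),
                 all.x = TRUE, sort = FALSE)
  pairs[, replicated := ifelse(is.na(p_repl), NA,
                               p_repl < p_thresh & sign(beta) == sign(beta_repl))]
  n_present <- sum(!is.na(pairs$replicated))
  n_repl <- sum(pairs$replicated, na.rm = TRUE)
  list(pairs = pairs[],
       n_discovery = nrow(pairs),
       n_present = n_present,
       n_replicated = n_repl,
       rate = if (n_present > 0) n_repl / n_present else NA_real_)
}

#' Replication rate by decile of discovery R-squared
#'
#' Pairs with known replication status are binned by deciles of the
#' discovery partial R2 (ties fall in the lower decile; only occupied,
#' distinct deciles are reported) and the replication rate is computed per
#' decile.
#'
#' @param pairs the \code{pairs} table from [evaluate_replication()]
#'   (needs r2 and replicated).
#' @return data.table: decile, r2_lo, r2_hi, n, rate.
#' @export
replication_by_r2_decile <- function(pairs) {
  known <- pairs[!is.na(replicated)]
  if (nrow(known) < 10L) stop("need at least 10 pairs with replication status")
  br <- unique(stats::quantile(known$r2, probs = 0:10 / 10, names = FALSE))
  dec <- if (length(br) < 2L) rep(1L, nrow(known)) else
    cut(known$r2, breaks = br, include.lowest = TRUE, right = TRUE,
        labels = FALSE)
  known[, .decile := dec]
  out <- known[, .(r2_lo = min(r2), r2_hi = max(r2), n = .N,
                   rate = mean(replicated)), by = .(decile = .decile)]
  data.table::setorder(out, decile)
  out[]
}

#' Effect-size concordance between discovery and replication
#'
#' Pearson correlation of the discovery and replication betas, and the
#' fraction of pairs with matching effect direction (a zero beta counts as
#' a mismatch and is reported in \code{n_zero}).
#'
#' @param pairs pairs table with beta and beta_repl present.
#' @return list: pearson_r, direction_fraction, n, n_zero.
#' @export
effect_concordance <- function(pairs) {
  both <- pairs[!is.na(beta) & !is.na(beta_repl)]
  if (nrow(both) < 3L) stop("need at least 3 pairs with both betas")
  zero <- both$beta == 0 | both$beta_repl == 0
  list(pearson_r = stats::cor(both$beta, both$beta_repl),
       direction_fraction = mean(sign(both$beta) == sign(both$beta_repl) & !zero),
       n = nrow(both), n_zero = sum(zero))
}

#' Overlap of irQTL genes with eQTL genes
#'
#' @param irqtl_genes,eqtl_genes character vectors of gene ids.
#' @return list: n_irqtl, n_overlap, proportion (share of irQTL genes that
#'   also carry an eQTL), percent.
#' @export
gene_overlap_summary <- function(irqtl_genes, eqtl_genes) {
  irqtl_genes <- unique(irqtl_genes)
  n_ov <- sum(irqtl_genes %in% unique(eqtl_genes))
  prop <- n_ov / length(irqtl_genes)
  list(n_irqtl = length(irqtl_genes), n_overlap = n_ov,
       proportion = prop, percent = 100 * prop)
}
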