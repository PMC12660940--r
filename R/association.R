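#' Minor allele frequency from dosages
#'
#' Alternate-allele frequency is the mean dosage over non-missing samples
#' divided by 2, folded to \code{min(f, 1 - f)}.
#'
#' @param dosages numeric vector in [0, 2], NA allowed.
#' @return folded MAF in [0, 0.5].
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all dosages missing")
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Hardy-Weinberg exact test
#'
#' Exact test p-value by enumeration over heterozygote counts conditional on
#' the allele counts (Wigginton-style: the p-value is the sum of the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact-test p-value in (0, 1].
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0L) stop("no genotypes")
  m <- min(2L * n_hom_alt + n_het, 2L * n_hom_ref + n_het)  # minor allele count
  if (m == 0L) return(1)
  h <- seq.int(m %% 2L, m, by = 2L)
  # log P(het = h | n, m), hom-minor = (m - h)/2, hom-major = n - (m + h)/2
  lp <- h * log(2) + lfactorial(n) -
    lfactorial((m - h) / 2) - lfactorial(h) - lfactorial(n - (m + h) / 2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- pr[match(n_het, h)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Trans-irQTL significance threshold
#'
#' Bonferroni bound over every transcript x SNP test:
#' \code{alpha / (n_transcripts * n_snps)}. At the discovery-scale counts of
#' 25,642 transcripts and 12,887,093 SNPs this gives ~1.5e-13.
#'
#' @param n_transcripts,n_snps positive test-grid dimensions.
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test threshold.
#' @export
trans_threshold <- function(n_transcripts, n_snps, alpha = 0.05) {
  if (n_transcripts <= 0 || n_snps <= 0) stop("counts must be positive")
  alpha / (n_transcripts * n_snps)
}

#' Classify a variant-transcript pair as cis or trans
#'
#' Cis: same chromosome and |pos - tss| <= window (boundary inclusive).
#' Trans: farther than the window, or a different chromosome (distance NA).
#'
#' @param snp_chrom,snp_pos variant location (vectorized).
#' @param tx_chrom,tx_tss transcript TSS location.
#' @param window cis window in bp (default 1e6).
#' @return data.table with \code{relation} ("cis"/"trans") and
#'   \code{distance} (bp, NA cross-chromosome).
#' @export
classify_relation <- function(snp_chrom, snp_pos, tx_chrom, tx_tss,
                              window = 1e6) {
  n <- max(length(snp_chrom), length(snp_pos), length(tx_chrom),
           length(tx_tss))
  snp_chrom <- rep_len(.norm_chrom(as.character(snp_chrom)), n)
  snp_pos <- rep_len(as.numeric(snp_pos), n)
  tx_chrom <- rep_len(.norm_chrom(as.character(tx_chrom)), n)
  tx_tss <- rep_len(as.numeric(tx_tss), n)
  same <- snp_chrom == tx_chrom
  dist <- ifelse(same, abs(snp_pos - tx_tss), NA_real_)
  data.table::data.table(
    relation = ifelse(same & dist <= window, "cis", "trans"),
    distance = dist)
}

#' Genotype principal components
#'
#' PCA of the standardized dosage matrix on an LD-thinned SNP subset (every
#' \code{thin}-th variant), monomorphic SNPs dropped. Scores are
#' deterministic up to sign; the sign is fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param genotypes a \code{genotype_data} object or samples x SNPs matrix.
#' @param k number of components (default 5); \code{k = 0} gives an empty
#'   covariate block.
#' @param thin keep every thin-th SNP (default 10).
#' @return samples x k score matrix.
#' @export
compute_genotype_pcs <- function(genotypes, k = 5, thin = 10) {
  x <- if (inherits(genotypes, "genotype_data")) genotypes$dosage else genotypes
  if (k == 0L) return(matrix(0, nrow(x), 0L, dimnames = list(rownames(x), NULL)))
  x <- x[, seq(1L, ncol(x), by = thin), drop = FALSE]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  sds <- apply(x, 2L, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  .pc_scores(scale(x), k)
}

#' Expression (or isoform-ratio) principal components
#'
#' PCA on the samples x features matrix with missing entries mean-imputed
#' per feature (imputation is for the PCA only); zero-variance features are
#' dropped.
#'
#' @param expr features x samples matrix, or an \code{isoform_ratios} object.
#' @param k number of components (default 15); must be below the sample count.
#' @return samples x k score matrix.
#' @export
compute_expression_pcs <- function(expr, k = 15) {
  m <- if (inherits(expr, "isoform_ratios")) expr$ratios else expr
  x <- t(m)  # samples x features
  if (k >= nrow(x)) stop("k must be smaller than the number of samples")
  if (k == 0L) return(matrix(0, nrow(x), 0L, dimnames = list(rownames(x), NULL)))
  for (j in seq_len(ncol(x))) {
    mis <- is.na(x[, j])
    if (any(mis)) x[mis, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2L, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  .pc_scores(scale(x), k)
}

.pc_scores <- function(xs, k) {
  sv <- svd(xs, nu = k, nv = k)
  if (k > sum(sv$d > sv$d[1L] * 1e-12)) stop("k exceeds matrix rank")
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
                  2L, flip, `*`)
  rownames(scores) <- rownames(xs)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Residualize a phenotype for family structure
#'
#' Two-step adjustment under a random-intercept-per-family model: variance
#' components are estimated by the one-way ANOVA (method-of-moments)
#' estimator, predicted family effects are the shrunken family means (BLUPs),
#' and the returned residuals are the phenotype minus the grand mean and the
#' predicted family effect. Singletons are residualized against the grand
#' mean only, so with no families at all this collapses to centering.
#'
#' @param y numeric phenotype; NAs are carried through.
#' @param family_ids family identifier per sample (singletons allowed).
#' @return residual vector, same length as \code{y}.
#' @export
residualize_family <- function(y, family_ids) {
  stopifnot(length(y) == length(family_ids))
  ok <- !is.na(y)
  out <- rep(NA_real_, length(y))
  yv <- y[ok]
  fam <- as.character(family_ids[ok])
  mu <- mean(yv)
  sizes <- table(fam)
  multi <- names(sizes)[sizes > 1L]
  if (!length(multi)) {
    out[ok] <- yv - mu
    return(out)
  }
  idx <- fam %in% multi
  fm <- tapply(yv[idx], fam[idx], mean)
  ni <- as.numeric(sizes[names(fm)])
  ssw <- sum((yv[idx] - fm[fam[idx]])^2)
  dfw <- sum(ni - 1)
  N <- sum(ni)
  a <- length(ni)
  ssb <- sum(ni * (fm - sum(ni * fm) / N)^2)
  sigma_w <- ssw / dfw
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  sigma_b <- max(0, (ssb / (a - 1) - sigma_w) / n0)
  shrink <- if (sigma_b > 0) ni * sigma_b / (ni * sigma_b + sigma_w) else rep(0, a)
  b <- stats::setNames(shrink * (fm - mu), names(fm))
  pred <- rep(0, sum(ok))
  pred[idx] <- b[fam[idx]]
  out[ok] <- yv - mu - pred
  out
}

#' Additive-dosage association fit
#'
#' OLS of the phenotype on \code{[1, dosage, covariates]} over complete
#' cases; the dosage coefficient is tested with a two-sided t-test and the
#' partial R-squared is \code{t^2 / (t^2 + df)}. Extreme statistics are
#' handled on the log scale (\code{log10_p}); a perfect fit reports the
#' smallest representable p.
#'
#' @param y phenotype vector (already family-residualized where applicable).
#' @param dosage alternate-allele dosage vector.
#' @param covariates optional numeric covariate matrix.
#' @return list with beta, se, t, p, log10_p, r2, df, n; or, when the dosage
#'   is constant on the complete cases, \code{skip = "monomorphic-in-analysis"}.
#' @export
fit_additive <- function(y, dosage, covariates = NULL) {
  n_all <- length(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n_all)
  }
  cc <- !is.na(y) & !is.na(dosage)
  if (!is.null(covariates)) cc <- cc & !rowSums(is.na(covariates))
  p_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (sum(cc) < p_cov + 3L) stop("too few complete cases")
  yv <- y[cc]
  d <- dosage[cc]
  if (stats::var(d) == 0) {
    return(list(skip = "monomorphic-in-analysis", n = sum(cc)))
  }
  X <- cbind(intercept = 1, dosage = d,
             if (!is.null(covariates)) covariates[cc, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # the dosage column itself is non-constant, so a deficient rank means
    # collinear covariates
    stop("rank-deficient covariate matrix")
  }
  df <- length(yv) - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom")
  coefs <- qr.coef(qx, yv)
  res <- qr.resid(qx, yv)
  rss <- sum(res^2)
  R <- qr.R(qx)
  xtx_inv_22 <- chol2inv(R)[2L, 2L]
  sigma2 <- rss / df
  beta <- coefs[["dosage"]]
  se <- sqrt(sigma2 * xtx_inv_22)
  .assoc_stats(beta, se, df, n = length(yv))
}

# shared t -> (p, log10_p, r2) conversion with underflow guards
.assoc_stats <- function(beta, se, df, n) {
  if (se == 0 || !is.finite(beta / se)) {
    tt <- Inf * sign(beta)
    return(list(beta = beta, se = se, t = tt, p = .Machine$double.xmin,
                log10_p = log10(.Machine$double.xmin), r2 = 1,
                df = df, n = n))
  }
  tt <- beta / se
  lp <- stats::pt(-abs(tt), df, log.p = TRUE) + log(2)
  p <- max(exp(lp), .Machine$double.xmin)
  list(beta = beta, se = se, t = tt, p = p, log10_p = lp / log(10),
       r2 = tt^2 / (tt^2 + df), df = df, n = n)
}

#' Default scan configuration
#'
#' @param maf_min common-variant MAF floor (default 0.01).
#' @param maf_rare rare band (exclusive bounds), default (0.003, 0.01).
#' @param hwe_min_p HWE exact-test floor (default 1e-10).
#' @param cis_window cis window around the TSS in bp (default 1e6).
#' @param cis_alpha cis significance level (default 5e-8).
#' @param trans_alpha trans significance level; when NULL it is derived from
#'   [trans_threshold()] on the actual test grid.
#' @param store_p storage threshold for emitted records (default 1e-4).
#' @param n_geno_pcs,n_expr_pcs numbers of genotype/expression PCs (5, 15).
#' @return list of scan settings.
#' @export
scan_config <- function(maf_min = 0.01, maf_rare = c(0.003, 0.01),
                        hwe_min_p = 1e-10, cis_window = 1e6,
                        cis_alpha = 5e-8, trans_alpha = NULL,
                        store_p = 1e-4, n_geno_pcs = 5L, n_expr_pcs = 15L) {
  stopifnot(cis_window > 0, cis_alpha > 0, store_p > 0)
  list(maf_min = maf_min, maf_rare = maf_rare, hwe_min_p = hwe_min_p,
       cis_window = cis_window, cis_alpha = cis_alpha,
       trans_alpha = trans_alpha, store_p = store_p,
       n_geno_pcs = n_geno_pcs, n_expr_pcs = n_expr_pcs)
}

#' Genome-wide additive irQTL scan
#'
#' Runs the additive-dosage regression of every isoform ratio on every
#' eligible SNP, with covariates partialled out per missingness pattern
#' (Frisch-Waugh residualization, numerically identical to the joint OLS
#' fit of [fit_additive()]). SNPs are pre-filtered by the mode's MAF band
#' (common >= \code{maf_min}; rare-cis inside \code{maf_rare}) and by HWE;
#' cis/rare-cis modes test pairs within the cis window of the transcript
#' TSS, trans mode tests all other pairs. Records with \code{p < store_p}
#' are returned with a significance flag at \code{cis_alpha} or the trans
#' threshold.
#'
#' @param genotypes \code{genotype_data}.
#' @param ratios \code{isoform_ratios} object (or any features x samples
#'   matrix plus \code{feature_meta}).
#' @param covariates samples x p numeric covariate matrix (age, sex, wbc,
#'   genotype PCs, expression PCs, ...); may be NULL.
#' @param config a [scan_config()] list.
#' @param mode one of "cis", "trans", "rare-cis".
#' @param family_ids optional family ids; when given, each phenotype is
#'   family-residualized before the regression.
#' @param feature_meta optional data.table(feature_id, gene_id, chrom, tss)
#'   when \code{ratios} is a bare matrix (used for the gene-level eQTL scan).
#' @return data.table of association records (snp, transcript, gene, chrom,
#'   pos, beta, se, t, p, log10_p, r2, n, relation, distance, significant).
#' @export
scan_irqtl <- function(genotypes, ratios, covariates = NULL,
                       config = scan_config(), mode = c("cis", "trans", "rare-cis"),
                       family_ids = NULL, feature_meta = NULL) {
  mode <- match.arg(mode)
  if (inherits(ratios, "isoform_ratios")) {
    Y <- ratios$ratios
    ann <- ratios$annotation
    feature_meta <- data.table::data.table(
      feature_id = ann$transcript_id, gene_id = ann$gene_id,
      chrom = ann$chrom, tss = ann$tss)
    feature_meta <- feature_meta[match(rownames(Y), feature_meta$feature_id)]
  } else {
    Y <- ratios
    stopifnot(!is.null(feature_meta))
    feature_meta <- feature_meta[match(rownames(Y), feature_meta$feature_id)]
  }
  v <- genotypes$variants
  keep <- if (mode == "rare-cis") {
    v$maf > config$maf_rare[1L] & v$maf < config$maf_rare[2L]
  } else {
    v$maf >= config$maf_min
  }
  keep <- keep & v$hwe_p >= config$hwe_min_p
  if (!any(keep)) {
    stop("no SNPs left after MAF/HWE filters (mode ", mode, ")")
  }
  v <- v[keep]
  D <- genotypes$dosage[, keep, drop = FALSE]
  n <- nrow(D)
  stopifnot(ncol(Y) == n)
  alpha <- if (mode == "trans") {
    config$trans_alpha %||% trans_threshold(nrow(Y), nrow(v))
  } else config$cis_alpha

  if (!is.null(family_ids)) {
    Y <- t(apply(Y, 1L, residualize_family, family_ids = family_ids))
  }
  Z <- cbind(rep(1, n), covariates)

  # group phenotypes by missingness pattern so covariate residualization of
  # the dosage matrix is done once per pattern
  pat_key <- apply(is.na(Y), 1L, function(m) paste(which(m), collapse = ","))
  out <- vector("list", 0L)
  for (key in unique(pat_key)) {
    tx_idx <- which(pat_key == key)
    smp <- if (key == "") seq_len(n) else
      setdiff(seq_len(n), as.integer(strsplit(key, ",")[[1L]]))
    if (length(smp) < ncol(Z) + 2L) next
    qz <- qr(Z[smp, , drop = FALSE])
    if (qz$rank < ncol(Z)) stop("rank-deficient covariate matrix")
    RD <- qr.resid(qz, D[smp, , drop = FALSE])
    den <- colSums(RD^2)
    testable <- den > 1e-10 * length(smp)
    RY <- qr.resid(qz, t(Y[tx_idx, smp, drop = FALSE]))
    df <- length(smp) - ncol(Z) - 1L
    rec <- .scan_block(RD, den, testable, RY, df, v, feature_meta[tx_idx],
                       mode, config, alpha, n_used = length(smp))
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  if (!length(out)) {
    return(.empty_records())
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, transcript, p)
  res[]
}

# vectorized per-pattern scan: RD samples x SNPs residualized dosages,
# RY samples x transcripts residualized phenotypes
.scan_block <- function(RD, den, testable, RY, df, variants, fmeta,
                        mode, config, alpha, n_used) {
  if (df < 1L) return(NULL)
  NUM <- crossprod(RD, RY)                # SNPs x transcripts
  ry2 <- colSums(RY^2)
  recs <- vector("list", ncol(RY))
  for (j in seq_len(ncol(RY))) {
    rel <- classify_relation(variants$chrom, variants$pos,
                             fmeta$chrom[j], fmeta$tss[j],
                             window = config$cis_window)
    snp_ok <- testable & (if (mode == "trans") rel$relation == "trans"
                          else rel$relation == "cis")
    if (!any(snp_ok)) next
    i <- which(snp_ok)
    num <- NUM[i, j]
    beta <- num / den[i]
    rss <- pmax(ry2[j] - num^2 / den[i], 0)
    sigma2 <- rss / df
    se <- sqrt(sigma2 / den[i])
    tt <- ifelse(se > 0, beta / se, Inf * sign(beta))
    lp <- (stats::pt(-abs(tt), df, log.p = TRUE) + log(2)) / log(10)
    p <- pmax(10^lp, .Machine$double.xmin)
    store <- p < config$store_p
    if (!any(store)) next
    i <- i[store]
    recs[[j]] <- data.table::data.table(
      snp = variants$id[i], transcript = fmeta$feature_id[j],
      gene = fmeta$gene_id[j], chrom = variants$chrom[i],
      pos = variants$pos[i], beta = beta[store], se = se[store],
      t = tt[store], p = p[store], log10_p = lp[store],
      r2 = ifelse(is.finite(tt[store]), tt[store]^2 / (tt[store]^2 + df), 1),
      n = n_used, df = df, relation = rel$relation[i],
      distance = rel$distance[i], significant = p[store] < alpha)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(NULL)
  data.table::rbindlist(recs)
}

.empty_records <- function() {
  data.table::data.table(
    snp = character(), transcript = character(), gene = character(),
    chrom = character(), pos = integer(), beta = numeric(), se = numeric(),
    t = numeric(), p = numeric(), log10_p = numeric(), r2 = numeric(),
    n = integer(), df = integer(), relation = character(),
    distance = numeric(), significant = logical())
}

#' Gene-level eQTL scan with the same engine
#'
#' Applies [scan_irqtl()] to log gene-level TMM expression (log2 of the
#' per-gene sum of isoform TMM values, +1 offset), so irQTL and eQTL
#' association strengths are directly comparable.
#'
#' @param genotypes \code{genotype_data}.
#' @param tmm TMM-normalized \code{expr_matrix} (transcripts x samples).
#' @param annotation transcript annotation (gene TSS is taken from the
#'   gene's first annotated transcript).
#' @inheritParams scan_irqtl
#' @return association records with gene-level features.
#' @export
scan_eqtl <- function(genotypes, tmm, annotation, covariates = NULL,
                      config = scan_config(), mode = c("cis", "trans"),
                      family_ids = NULL) {
  mode <- match.arg(mode)
  vals <- expr_values(tmm)
  ann <- annotation[match(rownames(vals), annotation$transcript_id)]
  genes <- unique(ann$gene_id)
  G <- rowsum(vals, ann$gene_id)[genes, , drop = FALSE]
  Y <- log2(G + 1)
  gmeta <- annotation[, .(chrom = chrom[1L], tss = tss[1L]), by = gene_id]
  fm <- data.table::data.table(feature_id = gmeta$gene_id,
                               gene_id = gmeta$gene_id,
                               chrom = gmeta$chrom, tss = gmeta$tss)
  scan_irqtl(genotypes, Y, covariates = covariates, config = config,
             mode = mode, family_ids = family_ids, feature_meta = fm)
}
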