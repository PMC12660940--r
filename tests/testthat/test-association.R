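test_that("MAF is the folded mean-dosage frequency", {
  expect_equal(compute_maf(c(0, 1, 2)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, 1)), 1 / 6)
  expect_equal(compute_maf(c(0, NA, 2)), 0.5)
  expect_error(compute_maf(c(NA_real_, NA_real_)), "missing")
})

# independent HWE oracle: conditional het-count distribution built by the
# upward recurrence P(h+2)/P(h) = 4 * hom_min * hom_maj / ((h+1)(h+2))
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  if (m == 0) return(1)
  h <- seq(m %% 2, m, by = 2)
  pr <- numeric(length(h))
  pr[1] <- 1
  for (k in seq_len(length(h) - 1)) {
    hk <- h[k]
    pr[k + 1] <- pr[k] * 4 * ((m - hk) / 2) * ((2 * n - m - hk) / 2) /
      ((hk + 1) * (hk + 2))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

test_that("HWE exact test matches the recurrence oracle", {
  # modal het count -> p = 1; gross het deficit fails the QC filter
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(50, 0, 50), 1e-10)
  expect_equal(hwe_test(100, 0, 0), 1)  # monomorphic: single outcome
  expect_error(hwe_test(-1, 5, 5), "non-negative")
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:400, 1)
    g <- stats::rmultinom(1, n, prob = c(0.3, 0.45, 0.25))
    expect_equal(hwe_test(g[1], g[2], g[3]), hwe_oracle(g[1], g[2], g[3]),
                 tolerance = 1e-12)
  }
})

test_that("trans threshold is the Bonferroni bound over the test grid", {
  expect_equal(trans_threshold(1, 1, 0.05), 0.05)
  expect_equal(trans_threshold(10, 10, 0.05), 5e-4)
  expect_error(trans_threshold(0, 10), "positive")
})

test_that("cis/trans classification honors the 1 Mb inclusive boundary", {
  r <- classify_relation("1", c(1e6, 2e6 - 1, 2e6, 2e6 + 1), "1", 1e6)
  expect_equal(r$relation, c("cis", "cis", "cis", "trans"))
  expect_equal(r$distance, c(0, 999999, 1e6, 1000001))
  r2 <- classify_relation("2", 100, "1", 100)
  expect_equal(r2$relation, "trans")
  expect_true(is.na(r2$distance))
})

test_that("family residualization collapses to centering for singletons and
           removes family clustering", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(residualize_family(y, paste0("i", 1:5)), y - mean(y))
  # 200 sib pairs, ICC 0.5: the BLUP two-step shrinks each pair mean by
  # lambda = 2*s_b^2/(2*s_b^2 + s_w^2) = 2/3, leaving a residual ICC of
  # (1-lambda)*rho/(1-lambda*rho) = 1/7 -- assert the reduction to that
  # analytic level (one-way ANOVA ICC estimator)
  set.seed(41)
  fam <- rep(sprintf("f%03d", 1:200), each = 2)
  b <- stats::rnorm(200, 0, 1)
  y2 <- b[as.integer(factor(fam))] + stats::rnorm(400, 0, 1)
  icc <- function(v, f) {
    m <- tapply(v, f, mean)
    msb <- 2 * stats::var(m)
    msw <- sum((v - m[f])^2) / length(m)
    (msb - msw) / (msb + msw)
  }
  res <- residualize_family(y2, fam)
  expect_gt(icc(y2, fam), 0.4)
  expect_lt(icc(res, fam), 0.2)
  expect_lt(icc(res, fam), icc(y2, fam) / 2)
  # NA carried through
  y2[7] <- NA
  expect_true(is.na(residualize_family(y2, fam)[7]))
})

test_that("moment-based family residuals agree with lme4 BLUP residuals", {
  set.seed(43)
  fam <- c(rep(sprintf("f%02d", 1:60), each = 2), sprintf("s%02d", 1:80))
  b <- stats::rnorm(60, 0, 0.8)
  y <- c(b[as.integer(factor(fam[1:120]))], rep(0, 80)) + stats::rnorm(200)
  fit <- lme4::lmer(y ~ 1 + (1 | fam), REML = TRUE)
  res_lmer <- y - stats::predict(fit)
  res_mom <- residualize_family(y, fam)
  # REML and the moment estimator differ slightly in the variance split,
  # so the BLUP residuals agree closely but not exactly
  expect_gt(stats::cor(res_lmer, res_mom), 0.95)
})

test_that("fit_additive matches the normal-equations oracle", {
  # 8-point worked instance with one covariate
  y <- c(1.2, 0.8, 2.1, 1.9, 3.2, 2.8, 3.9, 4.1)
  d <- c(0, 0, 1, 1, 2, 2, 2, 2)
  z <- c(0.5, -0.2, 0.1, 0.7, -0.5, 0.2, 0.9, -0.1)
  X <- cbind(1, d, z)
  bh <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bh
  s2 <- sum(res^2) / (8 - 3)
  se_d <- sqrt(s2 * solve(crossprod(X))[2, 2])
  t_d <- bh[2] / se_d
  got <- fit_additive(y, d, cbind(z = z))
  expect_equal(got$beta, bh[2], tolerance = 1e-12)
  expect_equal(got$se, se_d, tolerance = 1e-12)
  expect_equal(got$p, 2 * stats::pt(-abs(t_d), 5), tolerance = 1e-12)
  expect_equal(got$r2, t_d^2 / (t_d^2 + 5), tolerance = 1e-12)
  # random full-rank instances, several covariates, missing entries
  set.seed(53)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    p <- sample(0:4, 1)
    d <- stats::rbinom(n, 2, 0.3)
    if (stats::var(d) == 0) next
    Z <- if (p) matrix(stats::rnorm(n * p), n) else NULL
    y <- 0.3 * d + stats::rnorm(n)
    y[sample(n, 2)] <- NA
    cc <- !is.na(y)
    X <- cbind(1, d, Z)[cc, , drop = FALSE]
    bh <- solve(crossprod(X), crossprod(X, y[cc]))
    s2 <- sum((y[cc] - X %*% bh)^2) / (sum(cc) - ncol(X))
    se <- sqrt(s2 * solve(crossprod(X))[2, 2])
    got <- fit_additive(y, d, Z)
    expect_equal(got$beta, bh[2], tolerance = 1e-8)
    expect_equal(got$se, se, tolerance = 1e-8)
  }
})

test_that("fit_additive handles perfect fits, monomorphism and collinearity", {
  d <- c(0, 0, 1, 1, 2, 2)
  perfect <- fit_additive(2 + 3 * d, d)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$p, .Machine$double.xmin)  # underflow-guarded
  mono <- fit_additive(stats::rnorm(10), rep(1, 10))
  expect_equal(mono$skip, "monomorphic-in-analysis")
  expect_error(fit_additive(stats::rnorm(6), d, cbind(d, d * 2)),
               "rank-deficient")
  expect_error(fit_additive(stats::rnorm(3), c(0, 1, 2), cbind(1:3)),
               "complete cases")
})

test_that("r2 is increasing in |t| at fixed df and invariant to shuffling", {
  # r2 monotonicity
  dfs <- 20
  ts <- seq(0.1, 30, length.out = 50)
  r2 <- ts^2 / (ts^2 + dfs)
  expect_true(all(diff(r2) > 0))
  # permutation invariance of the fit
  set.seed(61)
  n <- 40
  d <- stats::rbinom(n, 2, 0.4)
  z <- stats::rnorm(n)
  y <- 0.5 * d + 0.3 * z + stats::rnorm(n)
  perm <- sample(n)
  a <- fit_additive(y, d, cbind(z))
  b <- fit_additive(y[perm], d[perm], cbind(z[perm]))
  expect_equal(a[c("beta", "se", "p", "r2")], b[c("beta", "se", "p", "r2")],
               tolerance = 1e-12)
})

test_that("principal components recover planted structure and edge cases", {
  set.seed(71)
  # expression batch shift on half the samples
  m <- matrix(stats::rnorm(100 * 60), 100, 60)
  batch <- rep(c(0, 1), each = 30)
  m[1:40, ] <- m[1:40, ] + 2 * matrix(batch, 40, 60, byrow = TRUE)
  m <- rbind(m, const = rep(3, 60))  # zero-variance feature is dropped
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  pcs <- compute_expression_pcs(m, k = 5)
  expect_gt(max(abs(stats::cor(pcs, batch))), 0.8)
  expect_error(compute_expression_pcs(m, k = 60), "smaller than")
  # k = 0 gives an empty block the scan accepts
  g <- small_cohort()$genotypes
  p0 <- compute_genotype_pcs(g, k = 0)
  expect_equal(ncol(p0), 0L)
  # duplicated samples receive identical scores
  dup <- rbind(g$dosage[1:20, ], g$dosage[1:2, ])
  sc <- compute_genotype_pcs(dup, k = 3, thin = 1)
  expect_equal(sc[21, ], sc[1, ], tolerance = 1e-8)
  expect_equal(sc[22, ], sc[2, ], tolerance = 1e-8)
})

test_that("the vectorized scan equals fit_additive pair by pair", {
  pr <- small_prepared()
  co <- pr$cohort
  rec <- scan_irqtl(co$genotypes, pr$ratios, pr$covariates, scan_config(),
                    "cis", family_ids = co$genotypes$family_id)
  expect_gt(nrow(rec), 5)
  set.seed(3)
  for (i in sample(nrow(rec), 5)) {
    r <- rec[i]
    y <- residualize_family(pr$ratios$ratios[r$transcript, ],
                            co$genotypes$family_id)
    ref <- fit_additive(y, co$genotypes$dosage[, r$snp], pr$covariates)
    expect_equal(r$beta, ref$beta, tolerance = 1e-8)
    expect_equal(r$se, ref$se, tolerance = 1e-8)
    expect_equal(r$p, ref$p, tolerance = 1e-6)
    expect_equal(r$r2, ref$r2, tolerance = 1e-8)
  }
})

test_that("scan modes apply their MAF bands and relation masks", {
  pr <- small_prepared()
  co <- pr$cohort
  v <- co$genotypes$variants
  cis <- scan_irqtl(co$genotypes, pr$ratios, pr$covariates, scan_config(),
                    "cis", family_ids = co$genotypes$family_id)
  # no tested SNP below the common MAF floor; all pairs cis
  expect_true(all(v$maf[match(cis$snp, v$id)] >= 0.01))
  expect_true(all(cis$relation == "cis"))
  expect_true(all(cis$distance <= 1e6))
  trans <- scan_irqtl(co$genotypes, pr$ratios, pr$covariates, scan_config(),
                      "trans", family_ids = co$genotypes$family_id)
  expect_true(all(trans$relation == "trans"))
  # rare-cis band is exclusive on both sides
  rare <- tryCatch(
    scan_irqtl(co$genotypes, pr$ratios, pr$covariates, scan_config(),
               "rare-cis", family_ids = co$genotypes$family_id),
    error = function(e) NULL)
  if (!is.null(rare) && nrow(rare)) {
    mafs <- v$maf[match(rare$snp, v$id)]
    expect_true(all(mafs > 0.003 & mafs < 0.01))
  }
  # an impossible filter errors with the filter named
  strict <- scan_config(maf_min = 0.7)
  expect_error(scan_irqtl(co$genotypes, pr$ratios, pr$covariates, strict,
                          "cis"), "filters")
})

test_that("planted cis effects are recovered and gene-level eQTLs dissociate", {
  pr <- small_prepared()
  co <- pr$cohort
  cis <- scan_irqtl(co$genotypes, pr$ratios, pr$covariates, scan_config(),
                    "cis", family_ids = co$genotypes$family_id)
  sent <- select_cis_sentinels(cis, co$genotypes)
  rec <- irqtl:::.recovery_table(co$truth, cis, sent, co$genotypes)
  # primary plants only: transcripts carrying several stacked instruments
  # saturate and lose single-SNP marginal power by design
  strong <- rec[abs(usage_beta) >= 1.5 & maf >= 0.1 & primary == TRUE]
  expect_gt(nrow(strong), 0)
  expect_gte(mean(strong$detected), 0.8)
  expect_gte(mean(strong$sentinel_hit), 0.8)
  # the planted-usage SNP is not a gene-level eQTL (usage shifts preserve
  # gene totals), while the eQTL-only plant is
  eq <- scan_eqtl(co$genotypes, pr$tmm, co$annotation, pr$covariates,
                  scan_config(), "cis", family_ids = co$genotypes$family_id)
  eq_sig <- eq[significant == TRUE]
  expect_true(any(co$truth$eqtl_only$gene_id %in% eq_sig$gene))
  strongest <- co$truth$cis_irqtl[which.max(abs(usage_beta))]
  expect_false(nrow(eq_sig[snp == strongest$snp_id &
                             gene == strongest$gene_id]) > 0)
})
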