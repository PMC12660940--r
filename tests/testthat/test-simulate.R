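test_that("genotype simulation is deterministic and respects its config", {
  cfg <- small_config()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosage %in% 0:2))
  expect_equal(nrow(g1$variants), cfg$n_snps)
  # both cis-eligible and trans positions exist for every gene TSS
  ann <- simulate_annotation(cfg)
  v <- g1$variants
  has_cis <- vapply(unique(ann$gene_id), function(g) {
    gi <- ann[gene_id == g][1L]
    any(v$chrom == gi$chrom & abs(v$pos - gi$tss) <= 1e6)
  }, logical(1))
  expect_true(all(has_cis))
})

test_that("one homogeneous population is Hardy-Weinberg and binomial", {
  cfg <- sim_config(n_samples = 1000, n_snps = 2000, n_genes = 5,
                    n_populations = 1, family_fraction = 0, ld_rho = 0,
                    maf_range = c(0.1, 0.5), n_cis_irqtl = 0,
                    n_trans_irqtl = 0, n_eqtl_only = 0, seed = 11)
  gd <- simulate_genotypes(cfg)
  # mean genotype tracks twice the alternate-allele frequency by construction;
  # compare the realized het fraction with the binomial expectation 2p(1-p)
  f <- colMeans(gd$dosage) / 2
  het <- colMeans(gd$dosage == 1)
  expect_lt(max(abs(het - 2 * f * (1 - f))), 0.06)
  # exact-test p-values: conservative but never anti-conservative, and close
  # to uniform in Kolmogorov distance (the exact test is discrete, so exact
  # uniformity is not attainable)
  p <- gd$variants$hwe_p
  expect_lt(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(p)))
  expect_lt(mean(p < 0.01), 0.01 + 3 * sqrt(0.01 * 0.99 / length(p)))
  D <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(unname(D), 0.1)
})

test_that("LD blocks give higher adjacent than distant r2", {
  cfg <- sim_config(n_samples = 400, n_snps = 1000, n_genes = 5,
                    n_populations = 1, family_fraction = 0, ld_rho = 0.9,
                    maf_range = c(0.1, 0.5), n_cis_irqtl = 0,
                    n_trans_irqtl = 0, n_eqtl_only = 0, seed = 13)
  gd <- simulate_genotypes(cfg)
  d <- gd$dosage
  set.seed(1)
  idx <- sample(seq_len(ncol(d) - 1L), 200)
  adj <- vapply(idx, function(j) suppressWarnings(ld_r2(d[, j], d[, j + 1L])),
                numeric(1))
  far <- vapply(idx, function(j) {
    k <- ((j + 499L) %% ncol(d)) + 1L
    suppressWarnings(ld_r2(d[, j], d[, k]))
  }, numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE) + 0.2)
})

test_that("population divergence and sib pairs shape the cohort", {
  cfg <- sim_config(n_samples = 400, n_snps = 1500, n_genes = 5,
                    n_populations = 2, fst_like_divergence = 0.05,
                    family_fraction = 0.5, n_cis_irqtl = 0,
                    n_trans_irqtl = 0, n_eqtl_only = 0, seed = 17)
  gd <- simulate_genotypes(cfg)
  expect_equal(sum(table(gd$family_id) == 2L), 100L)  # 100 sib pairs
  # sibs share genotypes far beyond unrelated pairs
  fams <- names(which(table(gd$family_id) == 2L))
  sib_cor <- vapply(fams[1:40], function(f) {
    i <- which(gd$family_id == f)
    stats::cor(gd$dosage[i[1L], ], gd$dosage[i[2L], ])
  }, numeric(1))
  singles <- which(!gd$family_id %in% fams)
  unrel_cor <- vapply(1:40, function(k) {
    i <- sample(singles, 2L)
    stats::cor(gd$dosage[i[1L], ], gd$dosage[i[2L], ])
  }, numeric(1))
  expect_gt(mean(sib_cor), mean(unrel_cor) + 0.25)
  # genotype PC1 separates the two populations
  pcs <- compute_genotype_pcs(gd, k = 2)
  r <- abs(stats::cor(pcs[, 1L], gd$population))
  expect_gt(r, 0.9)
})

test_that("truth is consistent with the emitted data", {
  co <- small_cohort()
  tr <- co$truth
  expect_true(all(tr$cis_irqtl$snp_id %in% co$genotypes$variants$id))
  expect_true(all(tr$cis_irqtl$transcript_id %in% co$annotation$transcript_id))
  expect_true(all(tr$eqtl_only$gene_id %in% co$annotation$gene_id))
  # cis plants really are cis; trans plants on another chromosome
  v <- co$genotypes$variants
  ann <- co$annotation
  for (i in seq_len(nrow(tr$cis_irqtl))) {
    pl <- tr$cis_irqtl[i]
    rel <- classify_relation(v[id == pl$snp_id, chrom], v[id == pl$snp_id, pos],
                             ann[transcript_id == pl$transcript_id, chrom],
                             ann[transcript_id == pl$transcript_id, tss])
    expect_equal(rel$relation, "cis")
  }
  for (i in seq_len(nrow(tr$trans_irqtl))) {
    pl <- tr$trans_irqtl[i]
    expect_false(v[id == pl$snp_id, chrom] ==
                   ann[transcript_id == pl$transcript_id, chrom])
  }
  # planted QTL count exceeding the SNP count errors
  tiny <- sim_config(n_samples = 50, n_genes = 10, n_snps = 5,
                     n_cis_irqtl = 4, n_trans_irqtl = 2, n_eqtl_only = 3,
                     seed = 1)
  gd <- simulate_genotypes(tiny)
  expect_error(simulate_truth(gd, simulate_annotation(tiny), tiny),
               "planted QTL count")
})

test_that("eQTL-only plants move gene totals but leave usage untouched", {
  co <- small_cohort()
  pr <- small_prepared()
  # first eQTL-only gene with transcripts surviving the ratio filters
  surviving <- vapply(seq_len(nrow(co$truth$eqtl_only)), function(i) {
    any(co$annotation[gene_id == co$truth$eqtl_only$gene_id[i],
                      transcript_id] %in% rownames(pr$ratios$ratios))
  }, logical(1))
  expect_true(any(surviving))
  e <- co$truth$eqtl_only[which(surviving)[1L]]
  d <- co$genotypes$dosage[, e$snp_id]
  tx <- intersect(co$annotation[gene_id == e$gene_id, transcript_id],
                  rownames(pr$ratios$ratios))
  # gene total responds to dosage
  tot <- colSums(expr_values(pr$tmm)[
    intersect(co$annotation[gene_id == e$gene_id, transcript_id],
              rownames(expr_values(pr$tmm))), , drop = FALSE])
  fit_tot <- fit_additive(log2(tot + 1), d)
  expect_lt(fit_tot$p, 1e-6)
  # usage does not
  for (t1 in tx) {
    fit_r <- fit_additive(pr$ratios$ratios[t1, ], d)
    expect_gt(fit_r$p, 1e-4)
  }
})

test_that("library depth does not move isoform ratios", {
  co <- small_cohort()
  ex <- co$expression
  # multiply one sample's library size (and nothing else) by 10: FPKM for
  # that sample scales by 1/10 uniformly, TMM factors absorb it, ratios move
  # not at all
  ls2 <- ex$library_sizes
  ls2[5] <- ls2[5] * 10
  r1 <- compute_isoform_ratios(
    apply_tmm(compute_fpkm(ex$counts, ex$lengths, ex$library_sizes),
              compute_tmm_factors(compute_fpkm(ex$counts, ex$lengths,
                                               ex$library_sizes))),
    co$annotation)
  r2 <- compute_isoform_ratios(
    apply_tmm(compute_fpkm(ex$counts, ex$lengths, ls2),
              compute_tmm_factors(compute_fpkm(ex$counts, ex$lengths, ls2))),
    co$annotation)
  expect_equal(r1$ratios, r2$ratios, tolerance = 1e-9)
})

test_that("features, catalog and outcome generators obey their contracts", {
  co <- small_cohort()
  fc1 <- make_features_and_catalog(co$truth, co$genotypes$variants,
                                   enrichment_factor = 5, seed = 3)
  fc2 <- make_features_and_catalog(co$truth, co$genotypes$variants,
                                   enrichment_factor = 5, seed = 3)
  expect_identical(fc1$bed, fc2$bed)        # fixed seed, identical placement
  expect_identical(fc1$catalog, fc2$catalog)
  expect_error(make_features_and_catalog(co$truth, co$genotypes$variants,
                                         enrichment_factor = 0.5),
               "enrichment_factor")
  # every splice-feature variant sits inside a feature
  v <- co$genotypes$variants
  sp <- v[id %in% co$truth$splice_feature_snps]
  expect_true(all(feature_overlap(fc1$features, sp$chrom, sp$pos)))
  # outcome: gamma unset errors; otherwise two non-overlapping halves
  pr <- small_prepared()
  bad_truth <- co$truth
  bad_truth$causal <- bad_truth$causal[0]
  expect_error(simulate_outcome(pr$ratios, bad_truth, co$genotypes,
                                co$config), "gamma")
  om <- simulate_outcome(pr$ratios, co$truth, co$genotypes, co$config)
  expect_length(intersect(om$exposure_half, om$outcome_half), 0L)
  expect_equal(length(om$outcome), co$config$n_samples)
})
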