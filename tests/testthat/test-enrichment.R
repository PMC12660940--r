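test_that("bin assignment uses half-open cells with inclusive lowest edges", {
  bins <- match_bins()
  # (0.07, 50 kb) -> MAF cell (0.05, 0.1], distance cell (1e4, 1e5]
  cell <- assign_bin(0.07, 5e4, bins)
  expect_equal(bin_label(cell, bins), "maf(0.05,0.1] x dist(10000,100000]")
  # boundary conventions: the lowest edges belong to the first cell
  expect_equal(assign_bin(0.01, 0, bins), 1L)
  # the highest edges to the last cell
  nd <- length(bins$tss_dist_edges) - 1L
  nm <- length(bins$maf_edges) - 1L
  expect_equal(assign_bin(0.5, 1e6, bins), nm * nd)
  # interior upper edges belong to the cell below them (half-open cells)
  expect_equal(assign_bin(0.05, 1e3, bins), 1L)
  expect_equal(assign_bin(0.06, 1001, bins), nd + 2L)
  expect_error(assign_bin(0.6, 100, bins), "MAF outside")
  expect_error(assign_bin(0.2, 2e6, bins), "distance outside")
})

test_that("matched nulls share their sentinel's cell and are reproducible", {
  set.seed(77)
  pool <- data.table::data.table(
    snp = sprintf("p%04d", 1:3000),
    maf = stats::runif(3000, 0.01, 0.5),
    tss_dist = stats::runif(3000, 0, 1e6))
  sent <- pool[sample(.N, 10)]
  nulls <- sample_matched_nulls(sent, pool, n_sets = 50, seed = 5)
  expect_equal(dim(nulls), c(10L, 50L))
  # matching fidelity per draw
  s_cells <- assign_bin(sent$maf, sent$tss_dist)
  n_cells <- matrix(assign_bin(pool$maf[match(nulls, pool$snp)],
                               pool$tss_dist[match(nulls, pool$snp)]),
                    nrow(nulls))
  expect_true(all(n_cells == s_cells))
  # sentinels never sampled as their own nulls
  expect_false(any(nulls %in% sent$snp))
  # determinism under a fixed seed
  expect_identical(nulls, sample_matched_nulls(sent, pool, n_sets = 50,
                                               seed = 5))
  # empty cell errors, naming the cell
  lonely <- data.table::data.table(snp = "x1", maf = 0.45, tss_dist = 2)
  tiny_pool <- pool[maf < 0.3]
  expect_error(sample_matched_nulls(lonely, tiny_pool, n_sets = 5, seed = 1),
               "no pool SNPs in cell")
})

test_that("fold enrichment follows its formula and edge rules", {
  # observed 0.10 vs mean null 0.05 -> fold 2
  ov <- c(a = TRUE, b = FALSE, c = FALSE, d = FALSE, e = FALSE,
          f = FALSE, g = FALSE, h = FALSE, i = FALSE, j = FALSE,
          k = TRUE)
  sent <- names(ov)[1:10]           # observed = 0.1
  nulls <- matrix("b", 10, 4)       # null proportion 0 in each set...
  nulls[1, ] <- c("k", "b", "b", "b")  # sets: 0.1, 0, 0, 0 -> mean 0.025
  fe <- fold_enrichment(sent, nulls, ov)
  expect_equal(fe$observed_proportion, 0.1)
  expect_equal(fe$fold, 0.1 / 0.025)
  # feature covering everything -> fold 1
  ov_all <- stats::setNames(rep(TRUE, 11), names(ov))
  expect_equal(fold_enrichment(sent, nulls, ov_all)$fold, 1)
  # zero mean null with positive observed -> Inf with warning
  ov_only_sent <- stats::setNames(names(ov) == "a", names(ov))
  expect_warning(fe2 <- fold_enrichment(sent, matrix("b", 10, 4),
                                        ov_only_sent), "Inf")
  expect_equal(fe2$fold, Inf)
  # both zero -> NA
  ov_none <- stats::setNames(rep(FALSE, 11), names(ov))
  expect_true(is.na(fold_enrichment(sent, nulls, ov_none)$fold))
})

test_that("neutral feature placement centers fold enrichment on 1", {
  set.seed(83)
  n_pool <- 5000
  pool <- data.table::data.table(
    snp = sprintf("p%04d", 1:n_pool),
    maf = stats::runif(n_pool, 0.01, 0.5),
    tss_dist = 10^stats::runif(n_pool, 0, 6))
  folds <- vapply(1:120, function(r) {
    sent_i <- sample.int(n_pool, 200)
    ov <- stats::setNames(stats::runif(n_pool) < 0.05, pool$snp)
    nulls <- sample_matched_nulls(pool[sent_i], pool[-sent_i], n_sets = 60,
                                  seed = r)
    fold_enrichment(pool$snp[sent_i], nulls, ov)$fold
  }, numeric(1))
  expect_gt(mean(folds), 0.9)
  expect_lt(mean(folds), 1.1)
  # individual replicates concentrate near 1
  expect_gte(mean(folds > 0.5 & folds < 2), 0.95)
})

# exact two-sided Mann-Whitney p by enumeration of all group assignments
wilcox_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  r <- rank(pooled)
  Wobs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  Ws <- apply(idx, 2, function(i) sum(r[i]) - length(a) * (length(a) + 1) / 2)
  mu <- length(a) * length(b) / 2
  mean(abs(Ws - mu) >= abs(Wobs - mu) - 1e-12)
}

test_that("Wilcoxon comparison matches exact enumeration and detects shifts", {
  # identical 3-vs-3 distinct values: symmetric ranks give p = 1
  a <- c(1.0, 5.0, 9.0)
  b <- c(2.0, 6.0, 8.0)
  got <- compare_fold_distributions(a, b)
  expect_equal(got$p, wilcox_oracle(a, b), tolerance = 1e-12)
  # single-element groups: enumeration oracle decides the p
  expect_equal(compare_fold_distributions(1, 2)$p, wilcox_oracle(1, 2),
               tolerance = 1e-12)
  # more exact cases against the oracle
  set.seed(91)
  for (i in 1:10) {
    x <- round(stats::rnorm(sample(3:8, 1)), 3)
    y <- round(stats::rnorm(sample(3:8, 1), 0.5), 3)
    expect_equal(compare_fold_distributions(x, y)$p, wilcox_oracle(x, y),
                 tolerance = 1e-12)
  }
  # stochastic dominance gives a small p with the direction reported
  set.seed(92)
  lo <- stats::rnorm(60, 0)
  hi <- stats::rnorm(60, 1.2)
  sh <- compare_fold_distributions(hi, lo)
  expect_lt(sh$p, 1e-4)
  expect_equal(sh$direction, "a>b")
  # all values tied across both groups -> p = 1
  expect_equal(compare_fold_distributions(rep(2, 5), rep(2, 7))$p, 1)
})

test_that("catalog filters apply the significance and sample-size rules", {
  cat_tab <- data.table::data.table(
    snp = paste0("s", 1:5),
    p = c(1e-9, 1e-9, 1e-7, NA, 1e-9),
    n_discovery = c(12000, 6000, 50000, 20000, 6000),
    n_replication = c(NA, 4000, 20000, 10000, 6000))
  expect_message(out <- filter_catalog(cat_tab), "1 catalog record")
  # s1: big discovery, no replication -> kept; s2: both too small -> dropped;
  # s3: p too large -> dropped; s4: missing p -> dropped; s5: both >= 5000 -> kept
  expect_setequal(out$snp, c("s1", "s5"))
})

# two-sided Fisher p: sum of hypergeometric point masses not exceeding the
# observed mass (with the conventional relative-error guard)
fisher_oracle <- function(a, b, cc, d) {
  m <- a + cc; n <- b + d; k <- a + b
  x <- max(0, k - n):min(k, m)
  pm <- stats::dhyper(x, m, n, k)
  sum(pm[pm <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("Fisher enrichment builds the paper's table and matches the
           hypergeometric oracle", {
  u <- sprintf("u%05d", 1:10000)
  qtl <- u[1:110]
  cat_set <- u[c(1:10, 201:290)]
  fe <- fisher_enrichment(qtl, cat_set, u)
  expect_equal(unname(fe$table["catalog", "qtl"]), 10)
  expect_equal(unname(fe$table["catalog", "no_qtl"]), 90)
  expect_equal(unname(fe$table["no_catalog", "qtl"]), 100)
  expect_equal(unname(fe$table["no_catalog", "no_qtl"]), 9800)
  expect_equal(fe$odds_ratio, 10 * 9800 / (90 * 100))
  expect_equal(fe$p, fisher_oracle(10, 90, 100, 9800), tolerance = 1e-12)
  # independence-constructed table (a=10, b=90, cc=990, d=8910) has OR 1
  q2 <- u[1:1000]
  c2 <- u[c(1:10, 1001:1090)]
  fe2 <- fisher_enrichment(q2, c2, u)
  expect_equal(fe2$odds_ratio, 1)
  # empty intersection with large marginals -> OR 0, p from the oracle
  q3 <- u[1:50]
  c3 <- u[51:150]
  fe3 <- fisher_enrichment(q3, c3, u)
  expect_equal(fe3$odds_ratio, 0)
  expect_equal(fe3$p, fisher_oracle(0, 100, 50, 9850), tolerance = 1e-12)
  expect_error(fisher_enrichment(c("zz", u[1]), u[1:10], u), "subsets")
})

test_that("nearest TSS distance is the minimum over same-chromosome TSSs", {
  v <- data.table::data.table(chrom = c("1", "1", "2", "3"),
                              pos = c(150L, 900L, 500L, 100L))
  ann <- data.table::data.table(chrom = c("1", "1", "2"),
                                tss = c(100L, 1000L, 480L))
  d <- nearest_tss_distance(v, ann)
  expect_equal(d[1:3], c(50, 100, 20))
  expect_true(is.na(d[4]))
})
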