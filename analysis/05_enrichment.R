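# Functional enrichment of sentinel cis-irQTLs.
#
# Matched-null fold enrichment: 1000 null SNP sets drawn from the
# MAF x TSS-distance cell of each sentinel; fold = observed feature
# overlap over the mean null overlap. The same engine runs on the
# gene-level eQTL sentinels and the two fold distributions are compared
# with a two-sided Wilcoxon rank-sum test. Catalog enrichment: Fisher's
# exact test of sentinel SNPs against the filtered trait catalog over the
# scan-eligible SNP universe.

source("analysis/00_common.R")
seed <- arg_seed()
out <- results_dir(seed)
pc <- prepared_cohorts(seed)
d <- pc$discovery
co <- d$cohort
cfg <- scan_config()

cis_d <- scan_cache(seed, "cis_discovery", function()
  scan_irqtl(co$genotypes, d$ratios, d$covariates, cfg, "cis",
             family_ids = co$genotypes$family_id))
eqtl <- scan_cache(seed, "eqtl_discovery", function()
  scan_eqtl(co$genotypes, d$tmm, co$annotation, d$covariates, cfg, "cis",
            family_ids = co$genotypes$family_id))
sent <- select_cis_sentinels(cis_d, co$genotypes)
esent <- select_cis_sentinels(eqtl, co$genotypes)

fc <- make_features_and_catalog(co$truth, co$genotypes$variants,
                                enrichment_factor = 5, seed = seed + 5L)
v <- co$genotypes$variants
vdist <- nearest_tss_distance(v, co$annotation)
pool <- data.table(snp = v$id, maf = v$maf, tss_dist = vdist)[
  maf >= 0.01 & v$hwe_p >= 1e-10 & !is.na(tss_dist) & tss_dist <= 1e6]
ov <- stats::setNames(feature_overlap(fc$features, v$chrom, v$pos), v$id)

enrich_one <- function(stab, label) {
  sdt <- unique(data.table(snp = stab$snp, maf = v$maf[match(stab$snp, v$id)],
                           tss_dist = abs(stab$distance)), by = "snp")
  nulls <- sample_matched_nulls(sdt, pool, n_sets = 1000, seed = seed + 6L)
  fe <- fold_enrichment(sdt$snp, nulls, ov, feature = label)
  cat(sprintf("%s: observed overlap %.3f, mean null %.4f, fold = %.1f (n = %d sentinels)\n",
              label, fe$observed_proportion, mean(fe$null_proportions),
              fe$fold, nrow(sdt)))
  fe
}
fe_ir <- enrich_one(sent, "irQTL sentinels in splice features")
fe_eq <- enrich_one(esent, "eQTL sentinels in splice features")
wt <- compare_fold_distributions(fe_ir$fold_distribution,
                                 fe_eq$fold_distribution)
cat(sprintf("irQTL vs eQTL fold distributions: Wilcoxon W = %.0f, p = %.3g (%s)\n",
            wt$W, wt$p, wt$direction))

filt <- filter_catalog(fc$catalog)
fi <- fisher_enrichment(unique(cis_d[significant == TRUE, snp]),
                        unique(filt$snp), v$id)
cat(sprintf("catalog: %d/%d records pass the filters; Fisher OR = %.2f, p = %.3g\n",
            nrow(filt), nrow(fc$catalog), fi$odds_ratio, fi$p))

report <- data.table(
  measure = c("irqtl_fold", "eqtl_fold", "wilcoxon_p", "fisher_or",
              "fisher_p"),
  value = c(fe_ir$fold, fe_eq$fold, wt$p, fi$odds_ratio, fi$p))
fwrite(report, file.path(out, "enrichment_report.tsv"), sep = "\t")
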