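# Sentinel selection and discovery -> replication evaluation.
#
# Sentinels: per isoform the lowest-p cis variant (perfect-LD ties are
# co-sentinels); per isoform and SNP chromosome the lowest-p trans
# variant. A sentinel pair replicates when the replication cohort shows
# p < 1e-4 with the same effect direction; the rate is taken over pairs
# present in both cohorts, overall and by decile of discovery R2.

source("analysis/00_common.R")
seed <- arg_seed()
out <- results_dir(seed)
pc <- prepared_cohorts(seed)
d <- pc$discovery
r <- pc$replication
cfg <- scan_config()

cis_d <- scan_cache(seed, "cis_discovery", function()
  scan_irqtl(d$cohort$genotypes, d$ratios, d$covariates, cfg, "cis",
             family_ids = d$cohort$genotypes$family_id))
cis_r <- scan_cache(seed, "cis_replication", function()
  scan_irqtl(r$cohort$genotypes, r$ratios, r$covariates, cfg, "cis",
             family_ids = r$cohort$genotypes$family_id))
trans_d <- scan_cache(seed, "trans_discovery", function()
  scan_irqtl(d$cohort$genotypes, d$ratios, d$covariates, cfg, "trans",
             family_ids = d$cohort$genotypes$family_id))

sent <- select_cis_sentinels(cis_d, d$cohort$genotypes)
tsent <- select_trans_sentinels(trans_d)
ev <- evaluate_replication(sent, cis_r)
fwrite(sent, file.path(out, "cis_sentinels.tsv"), sep = "\t")
fwrite(tsent, file.path(out, "trans_sentinels.tsv"), sep = "\t")
fwrite(ev$pairs, file.path(out, "cis_replication_pairs.tsv"), sep = "\t")

cat(sprintf("cis sentinels: %d pairs over %d isoforms (%d with perfect-LD co-sentinels)\n",
            nrow(sent), length(unique(sent$transcript)),
            sum(table(sent$transcript) > 1L)))
cat(sprintf("trans sentinels: %d (isoform x SNP-chromosome)\n", nrow(tsent)))
cat(sprintf("replication: %d/%d pairs present in both cohorts replicated (rate %.1f%%)\n",
            ev$n_replicated, ev$n_present, 100 * ev$rate))

if (ev$n_present >= 10) {
  dec <- replication_by_r2_decile(ev$pairs)
  fwrite(dec, file.path(out, "replication_by_r2_decile.tsv"), sep = "\t")
  cat("replication rate by discovery-R2 decile:\n")
  print(dec)
}
if (sum(!is.na(ev$pairs$beta_repl)) >= 3) {
  cc <- effect_concordance(ev$pairs)
  cat(sprintf("effect concordance: Pearson r = %.3f, %.1f%% same direction (n = %d)\n",
              cc$pearson_r, 100 * cc$direction_fraction, cc$n))
}

# truth recovery for the planted cis effects
recov <- irqtl:::.recovery_table(d$cohort$truth, cis_d, sent,
                                 d$cohort$genotypes)
fwrite(recov, file.path(out, "recovery.tsv"), sep = "\t")
strong <- recov[abs(usage_beta) >= 1.5 & maf >= 0.1 & primary == TRUE]
cat(sprintf("recovery: %.0f%% of all planted cis pairs detected at 5e-8; strong primary plants (|beta| >= 1.5, MAF >= 0.1): %.0f%% detected, %.0f%% sentinel hits (n = %d)\n",
            100 * mean(recov$detected), 100 * mean(strong$detected),
            100 * mean(strong$sentinel_hit), nrow(strong)))
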