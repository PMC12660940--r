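# Genome-wide irQTL scans in the discovery cohort.
#
# Additive-dosage regression of each isoform ratio (family-residualized)
# on each eligible SNP, adjusting for age, sex, WBC, 5 genotype PCs and
# 15 expression PCs. Modes: common cis (MAF >= 0.01, +-1 Mb of the TSS,
# alpha 5e-8), trans (beyond 1 Mb or another chromosome, Bonferroni alpha
# over the full grid), rare cis (0.003 < MAF < 0.01), and a gene-level
# eQTL scan with the same engine on log gene TMM totals. Records with
# p < 1e-4 are stored.

source("analysis/00_common.R")
seed <- arg_seed()
out <- results_dir(seed)
pc <- prepared_cohorts(seed)
d <- pc$discovery
co <- d$cohort
cfg <- scan_config()

cis <- scan_cache(seed, "cis_discovery", function()
  scan_irqtl(co$genotypes, d$ratios, d$covariates, cfg, "cis",
             family_ids = co$genotypes$family_id))
trans <- scan_cache(seed, "trans_discovery", function()
  scan_irqtl(co$genotypes, d$ratios, d$covariates, cfg, "trans",
             family_ids = co$genotypes$family_id))
rare <- scan_cache(seed, "rare_discovery", function()
  tryCatch(scan_irqtl(co$genotypes, d$ratios, d$covariates, cfg, "rare-cis",
                      family_ids = co$genotypes$family_id),
           error = function(e) irqtl:::.empty_records()))
eqtl <- scan_cache(seed, "eqtl_discovery", function()
  scan_eqtl(co$genotypes, d$tmm, co$annotation, d$covariates, cfg, "cis",
            family_ids = co$genotypes$family_id))

write_summary(cis, file.path(out, "scan_cis.tsv"))
write_summary(trans, file.path(out, "scan_trans.tsv"))
write_summary(rare, file.path(out, "scan_rare_cis.tsv"))
write_summary(eqtl, file.path(out, "scan_eqtl.tsv"))

trans_alpha <- trans_threshold(nrow(d$ratios$ratios),
                               sum(co$genotypes$variants$maf >= 0.01 &
                                     co$genotypes$variants$hwe_p >= 1e-10))
cat(sprintf("cis: %d stored pairs, %d significant at 5e-8 (%d isoforms, %d genes)\n",
            nrow(cis), sum(cis$significant),
            length(unique(cis[significant == TRUE, transcript])),
            length(unique(cis[significant == TRUE, gene]))))
cat(sprintf("trans: %d stored pairs, %d significant at %.2e\n",
            nrow(trans), sum(trans$significant), trans_alpha))
cat(sprintf("rare cis: %d stored pairs, %d significant\n",
            nrow(rare), sum(rare$significant)))
cat(sprintf("gene-level eQTL: %d stored pairs, %d significant (%d genes)\n",
            nrow(eqtl), sum(eqtl$significant),
            length(unique(eqtl[significant == TRUE, gene]))))

# irQTL/eQTL dissociation: usage plants shift ratios, not gene totals
tr <- co$truth$cis_irqtl[primary == TRUE]
in_eqtl <- mapply(function(s, g) nrow(eqtl[snp == s & gene == g &
                                             significant == TRUE]) > 0,
                  tr$snp_id, tr$gene_id)
cat(sprintf("dissociation: %d/%d primary usage plants show NO significant gene-level eQTL at their SNP\n",
            sum(!in_eqtl), length(in_eqtl)))
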