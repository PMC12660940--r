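# Simulate the discovery and replication cohorts.
#
# Two cohorts share one variant map (positions, population allele
# frequencies) and one planted truth — cis and trans isoform-usage effects,
# eQTL-only effects, and a causal isoform-ratio -> outcome effect — while
# the individuals differ, mimicking a discovery study and an external
# replication study genotyped on the same variants.

source("analysis/00_common.R")
seed <- arg_seed()
out <- results_dir(seed)
pc <- prepared_cohorts(seed)

disc <- pc$discovery$cohort
v <- disc$genotypes$variants

fwrite(disc$truth$cis_irqtl, file.path(out, "truth_cis_irqtl.tsv"), sep = "\t")
fwrite(disc$truth$trans_irqtl, file.path(out, "truth_trans_irqtl.tsv"), sep = "\t")
fwrite(disc$truth$eqtl_only, file.path(out, "truth_eqtl_only.tsv"), sep = "\t")
fwrite(disc$annotation, file.path(out, "annotation.tsv"), sep = "\t")
fwrite(v, file.path(out, "variants_discovery.tsv"), sep = "\t")

common <- v[maf >= 0.01 & hwe_p >= 1e-10]
cat(sprintf("cohorts: %d samples x %d SNPs, %d genes / %d transcripts\n",
            nrow(disc$genotypes$dosage), nrow(v),
            length(unique(disc$annotation$gene_id)), nrow(disc$annotation)))
cat(sprintf("common scan-eligible SNPs (MAF >= 0.01, HWE p >= 1e-10): %d (%.1f%%)\n",
            nrow(common), 100 * nrow(common) / nrow(v)))
cat(sprintf("planted: %d cis irQTLs (%d primary), %d trans irQTLs, %d eQTL-only; causal transcript %s (gamma = %.1f)\n",
            nrow(disc$truth$cis_irqtl), sum(disc$truth$cis_irqtl$primary),
            nrow(disc$truth$trans_irqtl), nrow(disc$truth$eqtl_only),
            disc$truth$causal$transcript_id[1], disc$truth$causal$gamma[1]))
cat(sprintf("family structure: %d sib pairs; %d subpopulations\n",
            sum(table(disc$genotypes$family_id) == 2L),
            length(unique(disc$genotypes$population))))
cat("wrote truth tables, annotation and variant metadata to ", out, "\n")
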