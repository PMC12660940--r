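# Normalize transcript counts to isoform ratios.
#
# Counts -> FPKM (length and depth) -> TMM scale factors (doubly trimmed
# M-values against a reference sample) -> isoform ratios (each transcript's
# TMM over its gene's TMM sum, missing where the gene total is zero) ->
# transcript filters (population median TMM >= 2, < 20% missing, parent
# gene with more than one annotated transcript).

source("analysis/00_common.R")
seed <- arg_seed()
out <- results_dir(seed)
pc <- prepared_cohorts(seed)

d <- pc$discovery
co <- d$cohort
ex <- co$expression
fpkm <- compute_fpkm(ex$counts, ex$lengths, ex$library_sizes)
factors <- compute_tmm_factors(fpkm)
unfiltered <- compute_isoform_ratios(apply_tmm(fpkm, factors), co$annotation)
report <- attr(filter_transcripts(unfiltered), "report")
fwrite(report, file.path(out, "transcript_filter_report.tsv"), sep = "\t")

closure <- rowsum(ifelse(is.na(unfiltered$ratios), 0, unfiltered$ratios),
                  unfiltered$annotation$gene_id)
cat(sprintf("TMM scale factors: range %.3f-%.3f (geometric mean %.6f)\n",
            min(factors), max(factors), exp(mean(log(factors)))))
cat(sprintf("compositional closure: max |gene-sample ratio sum - 1| = %.2e\n",
            max(abs(closure[closure != 0] - 1))))
cat(sprintf("missing ratios (gene TMM total zero): %.2f%% of entries\n",
            100 * mean(is.na(unfiltered$ratios))))
cat(sprintf("filters: %d of %d transcripts kept (median TMM >= 2: %d fail; <20%% missing: %d fail; single-isoform gene: %d fail)\n",
            sum(report$kept), nrow(report),
            sum(report$median_tmm < 2), sum(report$missing_frac >= 0.2),
            sum(!report$multi_isoform)))
cat(sprintf("scan-ready ratio matrix: %d transcripts x %d samples\n",
            nrow(d$ratios$ratios), ncol(d$ratios$ratios)))
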