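#' @import data.table
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".decile", "age", "beta", "beta_repl", "chrom",
  "decile", "distance", "gene", "gene_id", "hwe_p", "id", "length",
  "maf", "n_at_min", "n_iso", "p", "p_repl", "pos", "px", "r2",
  "relation", "replicated", "se", "sex", "significant", "snp", "snp_id",
  "start", "strand", "transcript", "transcript_id", "tss", "tss_dist",
  "usage_beta", "wbc", "end"
))
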