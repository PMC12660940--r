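# shared small-cohort fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 7) {
  sim_config(n_samples = 200, n_genes = 40, n_snps = 2000,
             n_cis_irqtl = 6, n_trans_irqtl = 2, n_eqtl_only = 4,
             seed = seed)
}

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(small_config())
  }
  .fixture_env$cohort
}

# cohort + normalized ratios + covariates, cached
small_prepared <- function() {
  if (is.null(.fixture_env$prepared)) {
    co <- small_cohort()
    ex <- co$expression
    fpkm <- compute_fpkm(ex$counts, ex$lengths, ex$library_sizes)
    tmm <- apply_tmm(fpkm, compute_tmm_factors(fpkm))
    ratios <- filter_transcripts(compute_isoform_ratios(tmm, co$annotation))
    covs <- cbind(age = ex$covariates$age, sex = ex$covariates$sex,
                  wbc = ex$covariates$wbc,
                  compute_genotype_pcs(co$genotypes, 5),
                  compute_expression_pcs(ratios, 10))
    .fixture_env$prepared <- list(cohort = co, fpkm = fpkm, tmm = tmm,
                                  ratios = ratios, covariates = covs)
  }
  .fixture_env$prepared
}

write_toy_vcf <- function(path, ds = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (ds) "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  "sampA\tsampB\tsampC"))
  fmt <- if (ds) "GT:DS" else "GT"
  gt <- function(g, d) if (ds) paste0(g, ":", d) else g
  body <- c(
    paste("1", 100, "rs1", "A", "G", ".", ".", ".", fmt,
          gt("0/0", "0.00"), gt("0/1", "1.37"), gt("1/1", "2.00"),
          sep = "\t"),
    paste("1", 200, "rs2", "C", "T", ".", ".", ".", fmt,
          gt("0/1", "0.95"), gt("0/1", "1.05"), gt("0/0", "0.10"),
          sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}
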