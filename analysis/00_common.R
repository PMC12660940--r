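# Shared setup for the numbered analysis drivers: one study configuration,
# a results directory, and a cached cohort builder so each driver can run
# on its own. Run the drivers from the repository root, in order:
#   Rscript analysis/01_simulate_cohorts.R
#   Rscript analysis/02_normalize_ratios.R
#   ...
# Every driver accepts an optional --seed <int> (default 1).

suppressPackageStartupMessages({
  library(irqtl)
  library(data.table)
})

arg_seed <- function() {
  a <- commandArgs(trailingOnly = TRUE)
  i <- match("--seed", a)
  if (!is.na(i) && length(a) > i) as.integer(a[i + 1L]) else 1L
}

results_dir <- function(seed) {
  d <- file.path("results", sprintf("seed_%d", seed))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

study_config <- function(seed) sim_config(seed = seed)

cache_dir <- function(seed) {
  d <- file.path("scratch", "analysis_cache", sprintf("seed_%d", seed))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# cohorts and normalized ratios are rebuilt deterministically from the seed;
# a cache under scratch/ spares the later drivers the ~1 min rebuild
prepared_cohorts <- function(seed) {
  cache <- file.path(cache_dir(seed), "prepared.rds")
  if (file.exists(cache)) return(readRDS(cache))
  cfg <- study_config(seed)
  disc <- simulate_cohort(cfg)
  repl <- simulate_cohort(cfg, cohort_seed = cfg$seed + 1000L,
                          truth = disc$truth)
  prep <- function(cohort) {
    ex <- cohort$expression
    fpkm <- compute_fpkm(ex$counts, ex$lengths, ex$library_sizes)
    tmm <- apply_tmm(fpkm, compute_tmm_factors(fpkm))
    ratios <- filter_transcripts(compute_isoform_ratios(tmm, cohort$annotation))
    covs <- cbind(age = ex$covariates$age, sex = ex$covariates$sex,
                  wbc = ex$covariates$wbc,
                  compute_genotype_pcs(cohort$genotypes, 5),
                  compute_expression_pcs(ratios, 15))
    list(cohort = cohort, tmm = tmm, ratios = ratios, covariates = covs)
  }
  out <- list(discovery = prep(disc), replication = prep(repl), config = cfg)
  saveRDS(out, cache)
  out
}

scan_cache <- function(seed, name, builder) {
  cache <- file.path(cache_dir(seed), sprintf("%s.rds", name))
  if (file.exists(cache)) return(readRDS(cache))
  x <- builder()
  saveRDS(x, cache)
  x
}
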