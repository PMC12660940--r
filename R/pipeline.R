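#' Run the full synthetic irQTL analysis
#'
#' One-command demonstration: simulates a discovery and a replication
#' cohort on a shared variant map and planted truth, normalizes
#' (FPKM, TMM, isoform ratios, transcript filters), builds covariates
#' (age, sex, WBC, genotype PCs, expression PCs), scans in cis, trans,
#' rare-cis and gene-level eQTL modes, selects sentinels, evaluates
#' replication, measures matched-null feature enrichment and catalog
#' enrichment, and runs two-sample MR on the planted causal transcript.
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param stages character subset of
#'   c("scan_trans","scan_rare","eqtl","enrichment","mr") to run beyond
#'   the core cis pipeline (all by default).
#' @param out_dir optional directory for TSV outputs.
#' @param n_null_sets matched null sets for the enrichment stage
#'   (default 1000).
#' @param verbose log stage progress (default TRUE).
#' @return list with all stage outputs and a \code{recovery} table of
#'   planted cis effects versus scan findings.
#' @export
run_demo <- function(config = sim_config(),
                     stages = c("scan_trans", "scan_rare", "eqtl",
                                "enrichment", "mr"),
                     out_dir = NULL, n_null_sets = 1000L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  say("[simulate] discovery cohort (seed %d, n = %d)", config$seed,
      config$n_samples)
  disc <- simulate_cohort(config)
  say("[simulate] replication cohort")
  repl <- simulate_cohort(config, cohort_seed = config$seed + 1000L,
                          truth = disc$truth)

  prep <- function(cohort) {
    ex <- cohort$expression
    fpkm <- compute_fpkm(ex$counts, ex$lengths, ex$library_sizes)
    tmm <- apply_tmm(fpkm, compute_tmm_factors(fpkm))
    ratios <- filter_transcripts(compute_isoform_ratios(tmm, cohort$annotation))
    gpc <- compute_genotype_pcs(cohort$genotypes, k = 5)
    epc <- compute_expression_pcs(ratios, k = 15)
    covs <- cbind(age = cohort$expression$covariates$age,
                  sex = cohort$expression$covariates$sex,
                  wbc = cohort$expression$covariates$wbc, gpc, epc)
    list(cohort = cohort, tmm = tmm, ratios = ratios, covariates = covs)
  }
  say("[normalize] FPKM -> TMM -> ratios -> filters")
  d <- prep(disc)
  r <- prep(repl)
  say("[normalize] %d transcripts kept in discovery", nrow(d$ratios$ratios))

  cfg <- scan_config()
  say("[scan] cis discovery")
  cis_d <- scan_irqtl(disc$genotypes, d$ratios, d$covariates, cfg, "cis",
                      family_ids = disc$genotypes$family_id)
  say("[scan] cis replication")
  cis_r <- scan_irqtl(repl$genotypes, r$ratios, r$covariates, cfg, "cis",
                      family_ids = repl$genotypes$family_id)
  out <- list(config = config, truth = disc$truth,
              discovery = d, replication = r,
              cis_discovery = cis_d, cis_replication = cis_r)

  say("[sentinels] cis")
  sent <- select_cis_sentinels(cis_d, disc$genotypes, alpha = cfg$cis_alpha)
  out$cis_sentinels <- sent
  repres <- evaluate_replication(sent, cis_r, p_thresh = 1e-4)
  out$cis_replication_eval <- repres
  say("[replicate] cis rate %.1f%% (%d/%d present)",
      100 * (repres$rate %||% NA), repres$n_replicated, repres$n_present)
  if (nrow(repres$pairs[!is.na(replicated)]) >= 10L) {
    out$replication_deciles <- replication_by_r2_decile(repres$pairs)
  }
  if (nrow(repres$pairs[!is.na(beta_repl)]) >= 3L) {
    out$cis_concordance <- effect_concordance(repres$pairs)
  }

  if ("scan_trans" %in% stages) {
    say("[scan] trans discovery")
    out$trans_discovery <- scan_irqtl(disc$genotypes, d$ratios, d$covariates,
                                      cfg, "trans",
                                      family_ids = disc$genotypes$family_id)
    out$trans_sentinels <- select_trans_sentinels(out$trans_discovery)
  }
  if ("scan_rare" %in% stages) {
    say("[scan] rare cis discovery")
    out$rare_cis_discovery <- tryCatch(
      scan_irqtl(disc$genotypes, d$ratios, d$covariates, cfg, "rare-cis",
                 family_ids = disc$genotypes$family_id),
      error = function(e) .empty_records())
  }
  if ("eqtl" %in% stages) {
    say("[scan] gene-level eQTL discovery")
    out$eqtl_discovery <- scan_eqtl(disc$genotypes, d$tmm, disc$annotation,
                                    d$covariates, cfg, "cis",
                                    family_ids = disc$genotypes$family_id)
    if (nrow(sent)) {
      ir_genes <- unique(sent$gene)
      eq_genes <- unique(out$eqtl_discovery[significant == TRUE, gene])
      out$gene_overlap <- gene_overlap_summary(ir_genes, eq_genes)
    }
  }

  if ("enrichment" %in% stages && nrow(sent)) {
    say("[enrich] matched-null feature + catalog enrichment")
    fc <- make_features_and_catalog(disc$truth, disc$genotypes$variants,
                                    enrichment_factor = 5,
                                    seed = config$seed + 5L)
    v <- disc$genotypes$variants
    vdist <- nearest_tss_distance(v, disc$annotation)
    pool <- data.table::data.table(snp = v$id, maf = v$maf, tss_dist = vdist)[
      maf >= 0.01 & v$hwe_p >= 1e-10 & !is.na(tss_dist) & tss_dist <= 1e6]
    sdt <- data.table::data.table(snp = sent$snp, maf = v$maf[match(sent$snp, v$id)],
                                  tss_dist = abs(sent$distance))
    sdt <- unique(sdt, by = "snp")
    nulls <- sample_matched_nulls(sdt, pool, n_sets = n_null_sets,
                                  seed = config$seed + 6L)
    ov <- stats::setNames(feature_overlap(fc$features, v$chrom, v$pos), v$id)
    out$feature_enrichment <- fold_enrichment(sdt$snp, nulls, ov,
                                              feature = "splice_site")
    filt <- filter_catalog(fc$catalog)
    out$catalog_fisher <- fisher_enrichment(
      unique(cis_d[significant == TRUE, snp]), unique(filt$snp), v$id)
  }

  if ("mr" %in% stages && nrow(disc$truth$causal) &&
      disc$truth$causal$transcript_id[1L] %in% rownames(d$ratios$ratios)) {
    say("[mr] two-sample MR on the planted causal transcript")
    om <- simulate_outcome(d$ratios, disc$truth, disc$genotypes, config,
                           confounder_basis = disc$expression$confounder_basis)
    out$mr <- run_mr(om$stats, disc$genotypes)
    out$mr$true_gamma <- disc$truth$causal$gamma[1L]
  }

  out$recovery <- .recovery_table(disc$truth, cis_d, sent, disc$genotypes)
  if (!is.null(out_dir)) .write_demo(out, out_dir)
  say("[done] %.1f s elapsed", as.numeric(difftime(Sys.time(), t0, "secs")))
  out
}

# planted cis effects vs scan findings; sentinel_hit is TRUE when the
# transcript's sentinel is one of its planted SNPs or a perfect-LD proxy
# of one (a transcript with several planted SNPs has a single strongest
# sentinel, so the hit is judged against the whole planted set)
.recovery_table <- function(truth, cis_records, sentinels, genotypes) {
  if (!nrow(truth$cis_irqtl)) return(data.table::data.table())
  tr <- data.table::copy(truth$cis_irqtl)
  tr[, maf := genotypes$variants$maf[match(snp_id, genotypes$variants$id)]]
  tr[, detected := mapply(function(.snp, .tx) {
    nrow(cis_records[snp == .snp & transcript == .tx &
                       significant == TRUE]) > 0
  }, snp_id, transcript_id)]
  planted_by_tx <- split(tr$snp_id, tr$transcript_id)
  tr[, sentinel_hit := vapply(transcript_id, function(.tx) {
    sn <- sentinels[transcript == .tx, snp]
    planted <- planted_by_tx[[.tx]]
    if (!length(sn)) return(FALSE)
    any(vapply(sn, function(x) {
      x %in% planted || any(vapply(planted, function(ps) {
        isTRUE(suppressWarnings(
          ld_r2(genotypes$dosage[, x],
                genotypes$dosage[, ps])) >= 1 - 1e-9)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))]
  tr[]
}

.write_demo <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) if (!is.null(x) && is.data.frame(x)) {
    data.table::fwrite(x, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t")
  }
  wr(out$cis_sentinels, "cis_sentinels")
  wr(out$cis_replication_eval$pairs, "cis_replication_pairs")
  wr(out$replication_deciles, "replication_deciles")
  wr(out$recovery, "recovery")
  wr(out$trans_sentinels, "trans_sentinels")
  invisible(out_dir)
}

#' Log stage provenance
#'
#' Emits a structured one-line record of a stage's parameters, seed and
#' input-file hashes (MD5 via tools::md5sum), and returns it invisibly.
#'
#' @param stage stage name.
#' @param params named list of parameters.
#' @param seed integer seed in force.
#' @param files optional character vector of input paths to hash.
#' @return invisible list(stage, params, seed, hashes).
#' @export
log_provenance <- function(stage, params = list(), seed = NA_integer_,
                           files = character()) {
  hashes <- if (length(files)) tools::md5sum(files) else NULL
  line <- sprintf("stage=%s seed=%s %s%s", stage, seed,
                  paste(names(params), unlist(params), sep = "=",
                        collapse = " "),
                  if (length(hashes)) paste0(" md5=", paste(
                    basename(files), unname(hashes), sep = ":",
                    collapse = ",")) else "")
  message(line)
  invisible(list(stage = stage, params = params, seed = seed,
                 hashes = hashes))
}
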