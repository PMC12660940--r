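#' Synthetic cohort configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 1000 samples over two subpopulations with mild allele-frequency
#' divergence, 30\% of samples arranged as sibling pairs, 20,000 SNPs in
#' LD blocks on a 4-chromosome synthetic genome, 300 multi-isoform genes,
#' planted cis/trans isoform-usage effects spanning weak to strong on the
#' logit scale, and one causal isoform-ratio effect on a quantitative
#' outcome.
#'
#' @param n_samples,n_genes,n_snps cohort dimensions.
#' @param isoforms_per_gene inclusive range of isoforms per gene.
#' @param maf_range ancestral alternate-allele frequency range (0, 0.5].
#' @param ld_block_size,ld_rho haplotype LD block length (SNPs) and
#'   within-block adjacent-site correlation.
#' @param n_populations,fst_like_divergence number of subpopulations and the
#'   Balding-Nichols-style divergence of their allele frequencies.
#' @param family_fraction fraction of samples arranged as sibling pairs.
#' @param n_cis_irqtl,n_trans_irqtl,n_eqtl_only planted effect counts (one
#'   gene each).
#' @param usage_effect_range planted isoform-usage effect magnitude,
#'   logits per alternate allele.
#' @param expr_effect_range planted gene-expression effect magnitude,
#'   log2 units per allele.
#' @param libsize_cv coefficient of variation of sequencing depth.
#' @param nb_dispersion negative-binomial dispersion of counts (> 0).
#' @param outcome_causal_beta causal effect of the designated isoform ratio
#'   on the simulated outcome (per ratio unit).
#' @param n_mr_instruments planted cis SNPs on the causal transcript (in
#'   distinct, well-separated LD blocks), giving the MR stage several
#'   quasi-independent instruments (default 6).
#' @param seed integer seed fixing every stochastic stage.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 1000L, n_genes = 300L,
                       isoforms_per_gene = c(2L, 4L), n_snps = 20000L,
                       maf_range = c(0.01, 0.5), ld_block_size = 20L,
                       ld_rho = 0.8, n_populations = 2L,
                       fst_like_divergence = 0.02, family_fraction = 0.3,
                       n_cis_irqtl = 40L, n_trans_irqtl = 8L,
                       n_eqtl_only = 20L, usage_effect_range = c(0.5, 2.5),
                       expr_effect_range = c(0.2, 0.8), libsize_cv = 0.3,
                       nb_dispersion = 0.1, outcome_causal_beta = 1.0,
                       n_mr_instruments = 6L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              n_snps = as.integer(n_snps), maf_range = maf_range,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              n_populations = as.integer(n_populations),
              fst_like_divergence = fst_like_divergence,
              family_fraction = family_fraction,
              n_cis_irqtl = as.integer(n_cis_irqtl),
              n_trans_irqtl = as.integer(n_trans_irqtl),
              n_eqtl_only = as.integer(n_eqtl_only),
              usage_effect_range = usage_effect_range,
              expr_effect_range = expr_effect_range,
              libsize_cv = libsize_cv, nb_dispersion = nb_dispersion,
              outcome_causal_beta = outcome_causal_beta,
              n_mr_instruments = as.integer(n_mr_instruments),
              seed = as.integer(seed),
              n_chrom = 4L, chrom_len = 60e6)
  stopifnot(cfg$n_samples > 0, cfg$n_genes > 0, cfg$n_snps > 0,
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$family_fraction >= 0, cfg$family_fraction <= 1,
            cfg$fst_like_divergence >= 0, cfg$nb_dispersion > 0,
            cfg$isoforms_per_gene[1] >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a transcript annotation on the synthetic genome
#'
#' Genes are placed uniformly over the chromosomes with random strand;
#' each gene carries a number of isoforms drawn from
#' \code{isoforms_per_gene}, with exonic lengths uniform in 500-5000 bp.
#' All isoforms of a gene share the gene TSS side (spans overlap), so the
#' TSS follows the strand convention.
#'
#' @param config a [sim_config()].
#' @return annotation data.table (transcript_id, gene_id, chrom, strand,
#'   tss, length).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 1L)
  g <- config$n_genes
  chrom <- as.character(sample.int(config$n_chrom, g, replace = TRUE))
  tss <- as.integer(round(stats::runif(g, 1.5e6, config$chrom_len - 1.5e6)))
  strand <- sample(c("+", "-"), g, replace = TRUE)
  k <- sample(seq(config$isoforms_per_gene[1], config$isoforms_per_gene[2]),
              g, replace = TRUE)
  gene_id <- sprintf("gene%03d", seq_len(g))
  ann <- data.table::data.table(
    gene_id = rep(gene_id, k),
    chrom = rep(chrom, k), strand = rep(strand, k),
    tss = rep(tss, k))
  ann[, transcript_id := paste0(gene_id, ".", seq_len(.N)), by = gene_id]
  ann[, length := as.integer(round(stats::runif(.N, 500, 5000)))]
  data.table::setcolorder(ann, c("transcript_id", "gene_id", "chrom",
                                 "strand", "tss", "length"))
  ann[]
}

#' Simulate genotype dosages with LD, population structure and families
#'
#' Haplotypes are drawn through a Gaussian copula: within LD blocks of
#' \code{ld_block_size} adjacent sites the latent normals follow an AR(1)
#' process with correlation \code{ld_rho}; thresholds are the
#' population-specific allele frequencies, which diverge from a shared
#' ancestral frequency by a Balding-Nichols draw with parameter
#' \code{fst_like_divergence}. Within each population genotypes are in
#' Hardy-Weinberg equilibrium. \code{family_fraction} of the samples are
#' sibling pairs that inherit whole parental haplotypes per chromosome.
#'
#' The variant map (positions, ancestral and population allele
#' frequencies) is fixed by \code{config$seed} alone, while the sampled
#' individuals depend on \code{cohort_seed}; a replication cohort drawn
#' with a different \code{cohort_seed} therefore shares the variant map
#' (and any planted truth) with discovery but contains new people.
#'
#' @param config a [sim_config()].
#' @param cohort_seed seed for the individual draw (default
#'   \code{config$seed}; shift it to draw an independent cohort on the same
#'   variant map).
#' @return a \code{genotype_data} with per-variant MAF and HWE p computed
#'   from the realized dosages, plus \code{family_id} and \code{population}.
#' @export
simulate_genotypes <- function(config, cohort_seed = config$seed) {
  map <- .sim_variant_map(config)
  set.seed(cohort_seed)
  n <- config$n_samples
  n_pairs <- floor(config$family_fraction * n / 2)
  n_sib <- 2L * n_pairs
  n_unrel <- n - n_sib
  # founder haplotypes: 4 per sib-pair family, 2 per unrelated individual
  n_hap <- 4L * n_pairs + 2L * n_unrel
  # units (families and singletons) assigned to populations
  n_units <- n_pairs + n_unrel
  unit_pop <- rep_len(seq_len(config$n_populations), n_units)
  hap_pop <- c(rep(unit_pop[seq_len(n_pairs)], each = 4L),
               rep(unit_pop[n_pairs + seq_len(n_unrel)], each = 2L))

  per_chrom <- map$per_chrom
  chrom <- map$chrom
  pos <- map$pos
  thr <- map$thr

  rho <- config$ld_rho
  innov <- sqrt(1 - rho^2)
  H <- matrix(0L, n_hap, config$n_snps)
  start <- 0L
  for (c_i in seq_len(config$n_chrom)) {
    s_c <- per_chrom[c_i]
    if (!s_c) next
    z <- stats::rnorm(n_hap)
    for (j in seq_len(s_c)) {
      if (j > 1L && ((j - 1L) %% config$ld_block_size) != 0L) {
        z <- rho * z + innov * stats::rnorm(n_hap)
      } else if (j > 1L) {
        z <- stats::rnorm(n_hap)
      }
      H[, start + j] <- (z < thr[start + j, hap_pop]) + 0L
    }
    start <- start + s_c
  }

  dosage <- matrix(0L, n, config$n_snps)
  family_id <- character(n)
  population <- integer(n)
  # sib pairs: per chromosome each sib inherits one maternal and one
  # paternal founder haplotype
  chrom_idx <- split(seq_len(config$n_snps), chrom)[as.character(seq_len(config$n_chrom))]
  row_i <- 0L
  for (f in seq_len(n_pairs)) {
    hap0 <- 4L * (f - 1L)
    for (child in 1:2) {
      row_i <- row_i + 1L
      family_id[row_i] <- sprintf("fam%04d", f)
      population[row_i] <- unit_pop[f]
      for (c_i in seq_len(config$n_chrom)) {
        m <- hap0 + sample.int(2L, 1L)
        p <- hap0 + 2L + sample.int(2L, 1L)
        j <- chrom_idx[[c_i]]
        dosage[row_i, j] <- H[m, j] + H[p, j]
      }
    }
  }
  for (u in seq_len(n_unrel)) {
    row_i <- row_i + 1L
    hap0 <- 4L * n_pairs + 2L * (u - 1L)
    family_id[row_i] <- sprintf("ind%04d", u)
    population[row_i] <- unit_pop[n_pairs + u]
    dosage[row_i, ] <- H[hap0 + 1L, ] + H[hap0 + 2L, ]
  }

  ids <- sprintf("snp%05d", seq_len(config$n_snps))
  dimnames(dosage) <- list(sprintf("s%04d", seq_len(n)), ids)
  variants <- data.table::data.table(
    id = ids, chrom = chrom, pos = as.integer(pos),
    ref = "A", alt = "G",
    maf = apply(dosage, 2L, compute_maf),
    hwe_p = .hwe_from_dosage(dosage))
  new_genotype_data(dosage + 0, variants, family_id = family_id,
                    population = population)
}

# variant positions and population allele-frequency thresholds, fixed by
# config$seed alone so replication cohorts share the map
.sim_variant_map <- function(config) {
  set.seed(config$seed + 10L)
  per_chrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chrom + 1L)))
  chrom <- rep(as.character(seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(s)
    sort(sample.int(config$chrom_len, s))), use.names = FALSE)
  p0 <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  Fd <- config$fst_like_divergence
  P <- matrix(p0, config$n_snps, config$n_populations)
  if (Fd > 0 && config$n_populations > 1L) {
    for (k in seq_len(config$n_populations)) {
      P[, k] <- stats::rbeta(config$n_snps, p0 * (1 - Fd) / Fd,
                             (1 - p0) * (1 - Fd) / Fd)
    }
    P <- pmin(pmax(P, 1e-4), 1 - 1e-4)
  }
  list(per_chrom = per_chrom, chrom = chrom, pos = pos,
       thr = stats::qnorm(P))
}

#' Plant the true effects of the synthetic cohort
#'
#' Chooses disjoint genes for cis-irQTLs (a cis SNP shifting one isoform's
#' usage on the logit scale), trans-irQTLs (a SNP on another chromosome),
#' and eQTL-only effects (a cis SNP shifting total gene expression, leaving
#' usage untouched). One cis-irQTL transcript (the one with the strongest
#' planted usage effect) is designated causal for the simulated outcome
#' with effect \code{outcome_causal_beta}. The cis-irQTL SNPs double as the
#' splice-feature variants used by [make_features_and_catalog()].
#'
#' @param genotypes \code{genotype_data} from [simulate_genotypes()].
#' @param annotation annotation from [simulate_annotation()].
#' @param config a [sim_config()].
#' @return a \code{sim_truth} list: data.tables \code{cis_irqtl} (snp_id,
#'   transcript_id, gene_id, usage_beta), \code{trans_irqtl},
#'   \code{eqtl_only} (snp_id, gene_id, expr_beta), \code{causal}
#'   (transcript_id, gamma), and \code{splice_feature_snps}.
#' @export
simulate_truth <- function(genotypes, annotation, config) {
  set.seed(config$seed + 2L)
  v <- genotypes$variants
  total <- config$n_cis_irqtl + config$n_trans_irqtl + config$n_eqtl_only
  if (config$n_snps < total) stop("n_snps smaller than the planted QTL count")
  genes <- annotation[, .(chrom = chrom[1], tss = tss[1], n_iso = .N), by = gene_id]
  multi <- genes[n_iso >= 2L]
  if (nrow(multi) < config$n_cis_irqtl + config$n_trans_irqtl) {
    stop("not enough multi-isoform genes for the planted irQTLs")
  }
  picked <- sample(multi$gene_id,
                   config$n_cis_irqtl + config$n_trans_irqtl)
  cis_genes <- picked[seq_len(config$n_cis_irqtl)]
  trans_genes <- setdiff(picked, cis_genes)
  eqtl_genes <- sample(setdiff(genes$gene_id, picked), config$n_eqtl_only)

  draw_effect <- function(k, range) {
    stats::runif(k, range[1], range[2]) * sample(c(-1, 1), k, replace = TRUE)
  }
  pick_tx <- function(g) {
    tx <- annotation[gene_id == g, transcript_id]
    sample(tx, 1L)
  }
  pick_cis_snp <- function(g) {
    gi <- genes[gene_id == g]
    cand <- v[chrom == gi$chrom & abs(pos - gi$tss) <= 1e6 & maf >= 0.01, id]
    if (!length(cand)) stop("no cis SNP available for gene ", g)
    sample(cand, 1L)
  }
  cis <- data.table::data.table(
    gene_id = cis_genes,
    transcript_id = vapply(cis_genes, pick_tx, character(1)),
    snp_id = vapply(cis_genes, pick_cis_snp, character(1)),
    usage_beta = draw_effect(length(cis_genes), config$usage_effect_range),
    primary = TRUE)
  trans <- data.table::data.table(
    gene_id = trans_genes,
    transcript_id = vapply(trans_genes, pick_tx, character(1)),
    snp_id = vapply(trans_genes, function(g) {
      gi <- genes[gene_id == g]
      cand <- v[chrom != gi$chrom & maf >= 0.05, id]
      sample(cand, 1L)
    }, character(1)),
    usage_beta = draw_effect(length(trans_genes), config$usage_effect_range))
  eqtl <- data.table::data.table(
    gene_id = eqtl_genes,
    snp_id = vapply(eqtl_genes, pick_cis_snp, character(1)),
    expr_beta = draw_effect(length(eqtl_genes), config$expr_effect_range))
  causal <- if (nrow(cis)) {
    top <- cis[which.max(abs(usage_beta))]
    data.table::data.table(transcript_id = top$transcript_id,
                           gamma = config$outcome_causal_beta)
  } else data.table::data.table(transcript_id = character(), gamma = numeric())
  # extra planted cis SNPs on the causal transcript, in well-separated
  # positions, so MR has several quasi-independent instruments
  if (nrow(causal) && config$n_mr_instruments > 1L) {
    ct <- causal$transcript_id[1L]
    cg <- annotation[transcript_id == ct, gene_id][1L]
    gi <- genes[gene_id == cg]
    have <- cis[transcript_id == ct, snp_id]
    cand <- v[chrom == gi$chrom & abs(pos - gi$tss) <= 1e6 & maf >= 0.05 &
                !id %in% have]
    extra_pos <- v[match(have, id), pos]
    picked_extra <- character()
    for (j in sample.int(nrow(cand))) {
      if (all(abs(cand$pos[j] - extra_pos) >= 2.5e5)) {
        picked_extra <- c(picked_extra, cand$id[j])
        extra_pos <- c(extra_pos, cand$pos[j])
      }
      if (length(picked_extra) >= config$n_mr_instruments - 1L) break
    }
    if (length(picked_extra)) {
      # secondary instruments (primary = FALSE): several effects stacked on
      # one transcript can saturate its usage, so single-SNP recovery is
      # only guaranteed for the primary one-per-gene plants
      cis <- data.table::rbindlist(list(cis, data.table::data.table(
        gene_id = cg, transcript_id = ct, snp_id = picked_extra,
        usage_beta = draw_effect(length(picked_extra),
                                 config$usage_effect_range),
        primary = FALSE)))
    }
  }
  structure(list(cis_irqtl = cis, trans_irqtl = trans, eqtl_only = eqtl,
                 causal = causal, splice_feature_snps = cis$snp_id),
            class = "sim_truth")
}

#' Simulate transcript counts and covariates
#'
#' Gene total log2-expression is baseline + covariate effects (age, sex,
#' white blood cell count) + planted eQTL dosage effects + normal noise.
#' Isoform usage is the softmax of per-transcript baseline logits plus
#' \code{usage_beta * dosage} for planted irQTLs plus logistic-normal
#' noise, so ratios are compositional with monotone dosage trends. The
#' expected fragment count of a transcript is gene total x usage x
#' length(kb) x depth(millions), and counts are negative binomial with
#' shared dispersion. Transcripts hosting planted irQTLs get a
#' non-negative baseline logit and their genes a floor on baseline
#' expression, so planted effects are expressed above the downstream
#' median-TMM filter.
#'
#' @param genotypes,annotation,truth,config cohort pieces.
#' @param cohort_seed seed for this cohort's expression noise (default
#'   \code{config$seed}).
#' @return list with \code{counts} (\code{expr_matrix}), \code{lengths},
#'   \code{library_sizes}, \code{covariates} (data.table: age, sex, wbc)
#'   and \code{covariate_betas}.
#' @export
simulate_expression <- function(genotypes, annotation, truth, config,
                                cohort_seed = config$seed) {
  set.seed(cohort_seed + 3L)
  n <- config$n_samples
  tx <- annotation$transcript_id
  n_tx <- length(tx)
  iso_count <- table(annotation$gene_id)
  planted_iso <- c(truth$cis_irqtl$transcript_id, truth$trans_irqtl$transcript_id)
  single <- planted_iso[iso_count[annotation$gene_id[match(planted_iso, tx)]] < 2L]
  if (length(single)) {
    stop("planted irQTL on single-isoform gene: ", single[1L])
  }

  covariates <- data.table::data.table(
    age = round(stats::runif(n, 30, 80)),
    sex = stats::rbinom(n, 1L, 0.5),
    wbc = stats::rnorm(n, 6, 1.5))
  cov_betas <- c(age = 0.003, sex = 0.05, wbc = 0.04)

  genes <- unique(annotation$gene_id)
  b_g <- stats::setNames(stats::rnorm(length(genes), log2(30), 0.8), genes)
  cov_part <- with(covariates, cov_betas["age"] * (age - mean(age)) +
                     cov_betas["sex"] * sex + cov_betas["wbc"] * (wbc - mean(wbc)))
  planted_genes <- unique(c(truth$cis_irqtl$gene_id, truth$trans_irqtl$gene_id))
  b_g[planted_genes] <- pmax(b_g[planted_genes], log2(30))
  MU_G <- outer(b_g, cov_part, `+`)
  if (nrow(truth$eqtl_only)) {
    for (i in seq_len(nrow(truth$eqtl_only))) {
      e <- truth$eqtl_only[i]
      MU_G[e$gene_id, ] <- MU_G[e$gene_id, ] +
        e$expr_beta * genotypes$dosage[, e$snp_id]
    }
  }
  MU_G <- MU_G + matrix(stats::rnorm(length(MU_G), 0, 0.3), nrow(MU_G))
  total <- 2^MU_G  # linear-scale gene totals

  # isoform usage logits
  alpha <- stats::rnorm(n_tx, 0, 1)
  names(alpha) <- tx
  alpha[planted_iso] <- pmax(alpha[planted_iso], 0)
  L <- matrix(alpha, n_tx, n) +
    matrix(stats::rnorm(n_tx * n, 0, 0.4), n_tx, n)
  plant <- data.table::rbindlist(list(
    truth$cis_irqtl[, .(transcript_id, snp_id, usage_beta)],
    truth$trans_irqtl[, .(transcript_id, snp_id, usage_beta)]))
  if (nrow(plant)) {
    for (i in seq_len(nrow(plant))) {
      pl <- plant[i]
      L[match(pl$transcript_id, tx), ] <- L[match(pl$transcript_id, tx), ] +
        pl$usage_beta * genotypes$dosage[, pl$snp_id]
    }
  }
  EL <- exp(L)
  denom <- rowsum(EL, annotation$gene_id)
  usage <- EL / denom[match(annotation$gene_id, rownames(denom)), , drop = FALSE]
  # the causal transcript's latent usage noise: an exogenous variable that
  # genuinely causes part of the ratio variation, reusable downstream as a
  # confounder shared between the ratio and a simulated outcome
  confounder_basis <- if (nrow(truth$causal)) {
    i_ct <- match(truth$causal$transcript_id[1L], tx)
    L[i_ct, ] - alpha[i_ct] -
      (if (nrow(plant)) {
        pl_ct <- plant[transcript_id == tx[i_ct]]
        if (nrow(pl_ct)) {
          colSums(t(genotypes$dosage[, pl_ct$snp_id, drop = FALSE]) *
                    pl_ct$usage_beta)
        } else 0
      } else 0)
  } else NULL

  sdlog <- sqrt(log(1 + config$libsize_cv^2))
  depth <- stats::rlnorm(n, log(2e7) - sdlog^2 / 2, sdlog)
  len_kb <- annotation$length / 1e3
  MU <- total[match(annotation$gene_id, rownames(total)), , drop = FALSE] *
    usage * len_kb
  MU <- sweep(MU, 2L, depth / 1e6, `*`)
  counts <- matrix(stats::rnbinom(length(MU), mu = MU,
                                  size = 1 / config$nb_dispersion),
                   n_tx, n,
                   dimnames = list(tx, rownames(genotypes$dosage)))
  list(counts = expr_matrix(counts, "counts"),
       lengths = annotation$length,
       library_sizes = stats::setNames(depth, rownames(genotypes$dosage)),
       covariates = covariates,
       covariate_betas = cov_betas,
       confounder_basis = confounder_basis)
}

#' Synthetic genomic features and trait catalog
#'
#' Feature intervals are placed over every splice-feature variant (half
#' width \code{halfwidth} bp) plus \code{n_background} intervals centered
#' on random other variants, so a matched-null engine sees the planted
#' variants always inside a feature and pool variants at the background
#' rate. The catalog lists each planted QTL SNP with probability
#' \code{min(1, enrichment_factor * base_rate)} and every other variant
#' with probability \code{base_rate}; a fraction \code{pass_fraction} of
#' rows receives p-values and sample sizes that pass the catalog filters
#' of [filter_catalog()], the rest fail them.
#'
#' @param truth \code{sim_truth}.
#' @param variants variant table (the \code{variants} element of a
#'   \code{genotype_data}).
#' @param enrichment_factor catalog enrichment of planted QTLs (>= 1).
#' @param seed RNG seed for placement.
#' @param halfwidth feature half width in bp (default 10).
#' @param n_background number of background feature intervals (default 300).
#' @param base_rate catalog membership probability for background SNPs.
#' @param pass_fraction fraction of catalog rows passing the filters.
#' @return list with \code{features} (a \code{feature_set}), \code{bed}
#'   (0-based half-open data.table) and \code{catalog} (snp, trait, p,
#'   n_discovery, n_replication).
#' @export
make_features_and_catalog <- function(truth, variants, enrichment_factor = 5,
                                      seed = 1L, halfwidth = 10L,
                                      n_background = 300L, base_rate = 0.02,
                                      pass_fraction = 0.85) {
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  set.seed(seed)
  splice <- unique(truth$splice_feature_snps)
  bg <- sample(setdiff(variants$id, splice), min(n_background,
                                                 nrow(variants) - length(splice)))
  centers <- variants[match(c(splice, bg), id)]
  bed <- data.table::data.table(
    chrom = centers$chrom,
    start = pmax(0L, centers$pos - 1L - halfwidth),
    end = centers$pos + halfwidth)
  features <- new_feature_set(bed$chrom, bed$start + 1L, bed$end)

  planted <- unique(c(truth$cis_irqtl$snp_id, truth$trans_irqtl$snp_id,
                      truth$eqtl_only$snp_id))
  p_in <- ifelse(variants$id %in% planted,
                 min(1, enrichment_factor * base_rate), base_rate)
  in_cat <- stats::runif(nrow(variants)) < p_in
  cat_snp <- variants$id[in_cat]
  pass <- stats::runif(length(cat_snp)) < pass_fraction
  catalog <- data.table::data.table(
    snp = cat_snp,
    trait = "synthetic_trait",
    p = ifelse(pass, 1e-9, 1e-6),
    n_discovery = ifelse(pass, 50000L, 6000L),
    n_replication = ifelse(pass, 10000L, 4000L))
  list(features = features, bed = bed, catalog = catalog)
}

#' Simulate a quantitative outcome and two-sample GWAS summary statistics
#'
#' The outcome is \code{gamma} times the causal isoform ratio plus a
#' confounder correlated with the non-genetic part of that ratio plus
#' noise. Exposure summary statistics (per-SNP regression of the ratio on
#' dosage) are computed on one half of the samples and outcome summary
#' statistics on the other half, giving a non-overlapping two-sample
#' design. Candidate SNPs are the common variants within 1 Mb of the
#' causal transcript's TSS.
#'
#' @param ratios \code{isoform_ratios} containing the causal transcript.
#' @param truth \code{sim_truth} with a designated causal effect.
#' @param genotypes \code{genotype_data}.
#' @param config a [sim_config()].
#' @param confounder_beta effect of the shared confounder on the outcome
#'   (default 0.5); set 0 for no confounding.
#' @param confounder_basis exogenous confounder values, one per sample —
#'   normally the \code{confounder_basis} emitted by
#'   [simulate_expression()] (the causal transcript's latent usage noise,
#'   which causes part of the ratio variation and is independent of every
#'   genotype). When NULL, a proxy is built from the in-sample ratio
#'   residual.
#' @param noise_sd outcome residual standard deviation (default 1).
#' @param seed RNG seed for the outcome draw (default
#'   \code{config$seed + 4}); vary it to redraw outcomes on a fixed cohort.
#' @return list: \code{outcome} (length n), \code{stats} (data.table snp,
#'   chrom, pos, bx, se_bx, px, by, se_by, py), \code{exposure_half},
#'   \code{outcome_half}, \code{causal_transcript}.
#' @export
simulate_outcome <- function(ratios, truth, genotypes, config,
                             confounder_beta = 0.5, noise_sd = 1,
                             confounder_basis = NULL,
                             seed = config$seed + 4L) {
  if (!nrow(truth$causal) || is.na(truth$causal$gamma[1L])) {
    stop("causal effect (gamma) unset in truth")
  }
  set.seed(seed)
  tx <- truth$causal$transcript_id[1L]
  gamma <- truth$causal$gamma[1L]
  if (!tx %in% rownames(ratios$ratios)) {
    stop("causal transcript ", tx, " absent from the ratio matrix")
  }
  r <- ratios$ratios[tx, ]
  n <- length(r)
  csnp <- truth$cis_irqtl[transcript_id == tx, snp_id]
  d_causal <- genotypes$dosage[, csnp, drop = FALSE]
  # shared confounder: prefer the exogenous latent usage noise; otherwise
  # fall back to the in-sample non-genetic ratio residual (kept unscaled —
  # standardizing would amplify the coupling that in-sample
  # residualization induces between the two summary-stat halves)
  if (is.null(confounder_basis)) {
    ok <- !is.na(r)
    confounder_basis <- rep(0, n)
    confounder_basis[ok] <- stats::resid(stats::lm(r[ok] ~ d_causal[ok, ]))
  }
  u <- confounder_basis + stats::rnorm(n, 0, 0.5)
  outcome <- gamma * ifelse(is.na(r), mean(r, na.rm = TRUE), r) +
    confounder_beta * u + stats::rnorm(n, 0, noise_sd)

  ann <- ratios$annotation[transcript_id == tx]
  v <- genotypes$variants
  cand <- v[chrom == ann$chrom & abs(pos - ann$tss) <= 1e6 & maf >= 0.01]
  half_a <- seq_len(floor(n / 2))
  half_b <- setdiff(seq_len(n), half_a)
  ex <- .simple_scan(genotypes$dosage[half_a, cand$id, drop = FALSE], r[half_a])
  out <- .simple_scan(genotypes$dosage[half_b, cand$id, drop = FALSE],
                      outcome[half_b])
  stats_dt <- data.table::data.table(
    snp = cand$id, chrom = cand$chrom, pos = cand$pos,
    bx = ex$beta, se_bx = ex$se, px = ex$p,
    by = out$beta, se_by = out$se, py = out$p)
  list(outcome = outcome, stats = stats_dt,
       exposure_half = half_a, outcome_half = half_b,
       causal_transcript = tx)
}

# vectorized simple (single-predictor) regressions of y on each column of D
.simple_scan <- function(D, y) {
  ok <- !is.na(y)
  D <- D[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  dc <- sweep(D, 2L, colMeans(D))
  yc <- y - mean(y)
  sxx <- colSums(dc^2)
  sxy <- colSums(dc * yc)
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  df <- n - 2L
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tt <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(tt), df), n = n)
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_annotation()], [simulate_truth()] and [simulate_expression()]
#' under one configuration.
#'
#' @param config a [sim_config()].
#' @param cohort_seed seed for the individual/noise draws; shift it (with
#'   \code{truth} supplied) to produce an independent replication cohort on
#'   the same variant map and planted truth.
#' @param truth optional \code{sim_truth} to reuse (default: derived from
#'   this cohort's genotypes).
#' @return list: genotypes, annotation, truth, expression.
#' @export
simulate_cohort <- function(config = sim_config(), cohort_seed = config$seed,
                            truth = NULL) {
  genotypes <- simulate_genotypes(config, cohort_seed = cohort_seed)
  annotation <- simulate_annotation(config)
  if (is.null(truth)) truth <- simulate_truth(genotypes, annotation, config)
  expression <- simulate_expression(genotypes, annotation, truth, config,
                                    cohort_seed = cohort_seed)
  list(genotypes = genotypes, annotation = annotation, truth = truth,
       expression = expression, config = config)
}
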