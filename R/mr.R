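#' Greedy LD clumping of MR instruments
#'
#' Candidates sorted by exposure p ascending are processed greedily: the
#' best remaining SNP is retained and every SNP within \code{window} bp on
#' the same chromosome with LD r2 >= \code{r2_max} against it is
#' discarded. The retained set is pairwise independent at the threshold.
#'
#' @param candidates data.table with snp, chrom, pos and the exposure
#'   p-value column \code{px} (plus any summary-stat columns, carried
#'   through).
#' @param genotypes \code{genotype_data} holding the candidate dosages.
#' @param r2_max LD r2 exclusion threshold (default 0.001).
#' @param window clumping window in bp (default 10 Mb).
#' @return the retained rows of \code{candidates}, best-p first.
#' @export
clump_instruments <- function(candidates, genotypes, r2_max = 0.001,
                              window = 1e7) {
  if (!nrow(candidates)) stop("empty candidate set")
  cand <- candidates[order(px)]
  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  while (any(alive)) {
    i <- which(alive)[1L]
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= window)
    if (length(near)) {
      r2s <- vapply(near, function(j) {
        suppressWarnings(ld_r2(genotypes$dosage[, cand$snp[i]],
                               genotypes$dosage[, cand$snp[j]]))
      }, numeric(1))
      alive[near[!is.na(r2s) & r2s >= r2_max]] <- FALSE
    }
  }
  cand[keep]
}

#' Wald ratio estimate from a single instrument
#'
#' Estimate by/bx with the first-order standard error |se_by / bx|
#' (exposure uncertainty ignored, the standard two-sample convention) and
#' a two-sided z test.
#'
#' @param bx,se_bx exposure effect and SE.
#' @param by,se_by outcome effect and SE.
#' @return an \code{mr_summary} list (method "wald").
#' @export
wald_ratio <- function(bx, se_bx, by, se_by) {
  if (bx == 0) stop("irrelevant instrument: bx = 0")
  est <- by / bx
  se <- abs(se_by / bx)
  z <- if (est == 0) 0 else est / se
  .mr_summary("wald", est, se, 2 * stats::pnorm(-abs(z)), n = 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of by on bx through the origin with weights
#' 1/se_by^2; equivalently the inverse-variance-weighted mean of the
#' per-instrument Wald ratios. The fixed-effect standard error
#' 1/sqrt(sum(bx^2/se_by^2)) is inflated by sqrt(Q/(k-1)) when the
#' heterogeneity statistic exceeds its degrees of freedom (multiplicative
#' random effects; never deflated).
#'
#' @param instruments data.table with bx, se_bx, by, se_by (>= 2 rows).
#' @return an \code{mr_summary} list (method "ivw").
#' @export
mr_ivw <- function(instruments) {
  k <- nrow(instruments)
  if (k < 2L) stop("IVW needs >= 2 instruments; use wald_ratio()")
  w <- 1 / instruments$se_by^2
  bx <- instruments$bx
  by <- instruments$by
  est <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- 1 / sqrt(sum(w * bx^2))
  Q <- sum(w * (by - est * bx)^2)
  infl <- max(1, sqrt(Q / (k - 1)))
  se <- se_fe * infl
  .mr_summary("ivw", est, se, 2 * stats::pnorm(-abs(est / se)), n = k,
              Q = Q)
}

#' MR-Egger regression
#'
#' Weighted least squares of by on bx with an intercept (weights
#' 1/se_by^2) after orienting every instrument to bx >= 0. The slope is
#' the causal estimate; the intercept estimates average directional
#' pleiotropy with its own SE and p. Standard errors use the same
#' multiplicative random-effects inflation as [mr_ivw()] with k - 2
#' degrees of freedom.
#'
#' @param instruments data.table with bx, se_bx, by, se_by (>= 3 rows).
#' @return an \code{mr_summary} list (method "egger") with
#'   \code{egger_intercept}, \code{egger_intercept_se},
#'   \code{egger_intercept_p}.
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3L) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(instruments$bx)
  flip[flip == 0] <- 1
  bx <- instruments$bx * flip
  by <- instruments$by * flip
  w <- 1 / instruments$se_by^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  V <- solve(XtWX)
  coefs <- V %*% crossprod(X, w * by)
  res <- by - X %*% coefs
  Q <- sum(w * res^2)
  infl <- max(1, sqrt(Q / (k - 2)))
  se <- sqrt(diag(V)) * infl
  slope <- coefs[2L]
  icpt <- coefs[1L]
  out <- .mr_summary("egger", slope, se[2L],
                     2 * stats::pnorm(-abs(slope / se[2L])), n = k, Q = Q)
  out$egger_intercept <- icpt
  out$egger_intercept_se <- se[1L]
  out$egger_intercept_p <- 2 * stats::pnorm(-abs(icpt / se[1L]))
  out
}

.mr_summary <- function(method, estimate, se, p, n, Q = NA_real_) {
  list(method = method, estimate = unname(estimate), se = unname(se),
       p = unname(p), n_instruments = n, Q = Q,
       ci_lower = unname(estimate - stats::qnorm(0.975) * se),
       ci_upper = unname(estimate + stats::qnorm(0.975) * se),
       egger_intercept = NA_real_, egger_intercept_se = NA_real_,
       egger_intercept_p = NA_real_)
}

#' Two-sample MR on harmonized summary statistics
#'
#' Clumps the candidates, then applies the Wald ratio (one instrument),
#' IVW (two or more) and MR-Egger (three or more).
#'
#' @param stats_dt harmonized summary stats (snp, chrom, pos, bx, se_bx,
#'   px, by, se_by).
#' @param genotypes \code{genotype_data} for LD clumping.
#' @param r2_max clumping threshold (default 0.001).
#' @param px_max instrument exposure p ceiling (default 5e-8).
#' @return list: instruments, ivw (or wald) and egger summaries.
#' @export
run_mr <- function(stats_dt, genotypes, r2_max = 0.001, px_max = 5e-8) {
  cand <- stats_dt[!is.na(bx) & !is.na(by) & px < px_max & bx != 0]
  if (!nrow(cand)) stop("no instrument candidates below the exposure p ceiling")
  inst <- clump_instruments(cand, genotypes, r2_max = r2_max)
  main <- if (nrow(inst) >= 2L) mr_ivw(inst) else
    wald_ratio(inst$bx, inst$se_bx, inst$by, inst$se_by)
  egger <- if (nrow(inst) >= 3L) mr_egger(inst) else NULL
  list(instruments = inst, main = main, egger = egger)
}
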