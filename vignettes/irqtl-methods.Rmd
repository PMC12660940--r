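---
title: "Isoform-ratio QTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-ratio QTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the quantities it computes, the statistical models behind them, the
parameters a user might touch, what the synthetic cohorts do and do not
emulate, and the numerical and design decisions taken where more than one
reasonable choice existed.

## 1. From counts to isoform ratios

Transcript-level quantification starts from fragment counts. FPKM divides
each count by exonic length (kb) and sequencing depth (millions of mapped
reads); `compute_fpkm()` is exactly that formula, erroring on non-positive
library sizes. Between-sample normalization uses TMM scale factors
computed *on the FPKM matrix* (`compute_tmm_factors()`, through edgeR with
equal nominal library sizes so the trimmed-mean machinery acts on the FPKM
values directly): per-sample log2 ratios M and average log2 intensities A
against a reference sample are formed over transcripts positive in both,
doubly trimmed (30% on M, 5% on A), and the factor is 2 to the
precision-weighted mean M, rescaled to geometric mean 1. The reference
defaults to the sample whose upper quartile is closest to the mean upper
quartile. Computing TMM on FPKM rather than raw counts carries the usual
caveat that the precision weights treat the values as counts; we accept it
because the ratio construction downstream cancels any per-sample scale
anyway (see the depth-invariance property below).

The isoform ratio of transcript *k* in sample *j* is its TMM value divided
by the sum of TMM values over all isoforms of its parent gene, and is
missing exactly where that gene sum is zero. Two invariants follow and are
enforced by tests at tolerance 1e-9:

* **Compositional closure** — non-missing ratios of a gene sum to 1 per
  sample.
* **Depth invariance** — multiplying one sample's counts (or its library
  size) by any c > 0 leaves that sample's ratios unchanged: the factor
  passes through FPKM and TMM and cancels inside the gene quotient.

Transcripts enter the scan when their population median TMM is at least 2
(inclusive; the median is over all samples, zeros included), their missing
fraction is strictly below 20%, and the parent gene has more than one
annotated transcript. A gene whose other isoforms fail the filters keeps
its surviving transcript: the ratio remains well defined, and discarding
it would throw away a measured quantity.

## 2. The association scan

Each SNP × isoform test is an ordinary least-squares fit of the
(family-residualized) ratio on `[1, dosage, covariates]` over complete
cases, with the dosage coefficient tested two-sided against Student's *t*
and the partial variance explained computed as R² = t²/(t²+df). Default
covariates are age (years), sex (0/1), white blood cell count, 5 genotype
principal components (population stratification) and 15 expression
principal components (unmeasured expression confounders, computed on the
filtered ratio matrix with per-transcript mean imputation for the PCA
only). The scan engine residualizes the covariates out of the phenotype
and the dosage matrix once per missingness pattern (Frisch–Waugh), which
is numerically identical to the joint fit — a property test asserts
agreement with `fit_additive()` to 1e-8 — while keeping the genome-wide
scan a handful of BLAS calls.

Key settings (all in `scan_config()`):

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.01 | common-variant MAF floor |
| `maf_rare` | (0.003, 0.01) | rare band, both bounds exclusive |
| `hwe_min_p` | 1e-10 | Hardy–Weinberg exact-test floor |
| `cis_window` | 1e6 bp | cis distance from the isoform TSS, inclusive |
| `cis_alpha` | 5e-8 | cis significance |
| `trans_alpha` | derived | 0.05 / (transcripts × SNPs) |
| `store_p` | 1e-4 | storage threshold for emitted records |

Decisions worth stating:

* **"Within 1 Mb" is inclusive** (|pos − TSS| ≤ 1,000,000). The boundary
  has measure zero; we resolve it toward cis.
* **Family adjustment** is a two-step residualization, not a per-test
  mixed model: variance components of a random-intercept-per-family model
  are estimated by the one-way ANOVA moment estimator and the shrunken
  (BLUP) family means are subtracted; singletons reduce to grand-mean
  centering. This is fast, deterministic, and matches per-transcript use.
  Note the analytic limit: with sibling pairs of intraclass correlation
  rho, BLUP shrinkage leaves a residual ICC of (1−λ)ρ/(1−λρ) — about 1/7
  at ρ = 0.5 — which is the correct behaviour of the two-step, not a
  defect; only full fixed-effect demeaning would remove family
  correlation entirely, at the cost of all between-family information.
  The cross-check against lme4's REML BLUPs agrees to correlation > 0.95.
* **Expression PCs are computed on the filtered ratio matrix** (the
  quantity actually scanned); gene-level expression would be the natural
  alternative and differs little in the synthetic cohorts.
* **Underflow**: p-values are computed on the log scale
  (`pt(..., log.p = TRUE)`) and stored alongside `log10_p`; a perfect fit
  reports the smallest representable double rather than zero.
* **Genotype PCs** use every 10th SNP (a simple LD thinning), mean
  imputation of missing dosages, and a sign convention (largest-magnitude
  loading positive) that makes scores deterministic.
* **Monomorphic-in-analysis** dosages skip the record with a reason
  rather than erroring, since complete-case restriction can make a
  polymorphic SNP constant.

The gene-level eQTL scan (`scan_eqtl()`) reuses the identical engine on
log2 gene TMM totals, which is what makes irQTL-vs-eQTL contrasts (R²
comparisons, enrichment comparisons) internally consistent: planted
usage effects move ratios but leave gene totals untouched, and the
drivers report that dissociation directly.

The Hardy–Weinberg filter uses an exact test: the conditional
distribution of the heterozygote count given the allele counts, with the
p-value the sum of probabilities not exceeding the observed outcome's.
Exact-test p-values are discrete and conservative by construction — under
a true-HWE binomial oracle their distribution is visibly sub-uniform at
any realistic sample size — so the calibration tests assert conservative
(never anti-conservative) rejection rates and a small Kolmogorov
distance, plus exact agreement with an independent recurrence-based
enumeration.

## 3. Sentinels, replication, concordance

Sentinels are the lowest-p significant variant per isoform (cis) or per
isoform × SNP-chromosome (trans). Cis ties at the minimum p are emitted
as co-sentinels when their dosages are in perfect LD, operationalized as
r² ≥ 1 − 1e-9 because exact equality of floating-point correlations is
fragile. Trans ties are broken by smaller standard error, then
lexicographic SNP id, and recorded in a `"ties"` attribute for audit (the
rule is ours; nothing in the method dictates one).

Replication follows the two-part criterion — replication p < 1e-4 and the
same effect-direction — with the rate's denominator restricted to pairs
present in both cohorts' stored records; absent pairs are NA, never
failures. Decile curves bin pairs by discovery R² with ties to the lower
decile and report only occupied, distinct deciles (degenerate inputs with
a single distinct R² collapse to one bin). Effect concordance reports the
Pearson correlation of discovery and replication betas and the fraction
sharing a sign, with exact zeros counted as mismatches and tallied.

## 4. Matched-null enrichment

Null SNP sets are matched on MAF × TSS-distance cells with edges 0.01,
0.05, 0.1, 0.2, 0.3, 0.5 and 0, 1 kb, 10 kb, 100 kb, 1 Mb. Cells are
half-open `(lower, upper]` with the lowest edge inclusive, so MAF 0.01
and distance 0 are assignable. Each of the (default 1000) sets draws one
pool SNP per sentinel, uniformly within the sentinel's cell, with
replacement across sets; an empty cell is a hard error naming the cell —
no silent fallback to a neighbouring cell, which would quietly break the
matching. Sentinel TSS distance is the distance to its own isoform's TSS;
pool SNPs are matched on distance to the nearest annotated TSS (the
natural analogue when a pool SNP has no associated isoform). Fold
enrichment is observed proportion over mean null proportion; per-set
folds are kept for distribution comparisons, with NA where a set is
uninformative (both proportions zero) and +Inf flagged when only the
null side is zero.

Distribution comparisons use the two-sided Wilcoxon rank-sum test — exact
enumeration when both groups have at most 12 untied values, otherwise the
normal approximation with tie correction — and Fisher's exact test
handles catalog enrichment on the 2×2 table (overlap, catalog-only,
QTL-only, remainder) over the scan-eligible SNP universe, with the
sample odds ratio ad/bc reported alongside the exact p. Catalog records
must satisfy p < 5e-8 and either both discovery and replication sample
sizes ≥ 5000 or discovery ≥ 10,000.

## 5. Two-sample Mendelian randomization

Instrument selection is greedy LD clumping: candidates sorted by exposure
p, the best retained, everything within 10 Mb at r² ≥ 0.001 discarded,
repeated. The r² threshold is part of the method; the 10 Mb window is our
choice (generous enough to cover any cis region). At desk-scale cohort
sizes, note that the sample r² between truly independent SNPs has
expectation 1/n, so a 0.001 threshold prunes aggressively when n is only
a few hundred — clumped instrument counts of 2–4 from 5–6 quasi-
independent planted SNPs are expected behaviour, not a bug.

Estimators use the standard first-order two-sample conventions: the Wald
ratio by/bx with se |se_y/bx| (exposure uncertainty ignored), IVW as the
weighted origin regression of by on bx with weights 1/se_y², and MR-Egger
as the weighted regression with intercept after orienting every
instrument to bx ≥ 0. Standard errors are fixed-effect, inflated by
sqrt(Q/(k−1)) (Egger: k−2) only when heterogeneity exceeds its degrees of
freedom — multiplicative random effects, never deflation. Known
limitations we accept with those conventions: regression dilution and
winner's curse (instruments are selected and estimated in the same
exposure half) attenuate the estimate by a few percent to ~15% at n =
400–1000, and Egger's orientation step biases its intercept upward when
instruments are weak enough for sign errors. Both effects shrink with
instrument strength and are visible, at the expected magnitude, in the
calibration results.

## 6. What the synthetic cohorts emulate — and what they do not

`sim_config()` defaults define the study conditions used throughout the
tests and drivers: n = 1000 samples, 300 genes with 2–4 isoforms, 20,000
SNPs on a 4-chromosome, 60 Mb-per-chromosome genome; MAF uniform on
(0.01, 0.5); LD blocks of 20 SNPs with AR(1) latent correlation 0.8
through a Gaussian copula; two subpopulations with Balding–Nichols
divergence 0.02; 30% of samples as sibling pairs inheriting whole
parental haplotypes per chromosome; 40 cis and 8 trans usage effects of
0.5–2.5 logits per allele plus 20 eQTL-only effects of 0.2–0.8 log2
units; negative-binomial counts with dispersion 0.1 and log-normal depth
(CV 0.3, mean 20M reads); and one isoform ratio causally driving a
quantitative outcome with effect 1.0 per ratio unit, confounded by the
transcript's own latent usage noise. These are desk-scale stand-ins
chosen once for realism at a size a laptop can iterate on; a full cohort
pipeline run takes about a minute on one CPU.

Isoform usage is the softmax of per-transcript logits (baseline +
planted dosage effects + logistic-normal noise), which guarantees
compositional ratios and monotone dosage–ratio trends. Two consequences
deserve emphasis. First, usage effects cancel in the gene total, so
planted irQTLs are genuinely invisible to the eQTL scan — the
dissociation the method is designed to expose. Second, softmax
saturates: a transcript carrying several strong logit effects (as the
designated causal transcript does, to furnish multiple MR instruments)
spends much of its dosage range near ratio 0 or 1, where the marginal
effect of any one SNP vanishes. The truth table therefore distinguishes
`primary` one-per-gene plants, for which single-SNP recovery at 5e-8 is
asserted, from the stacked secondary instruments, for which it is not.

The generator does **not** emulate: realistic LD maps or recombination
within chromosomes (sibs inherit whole parental haplotypes), sex
chromosomes and dosage compensation, read-level artifacts (GC content,
positional bias, mapping ambiguity between isoforms — arguably the
hardest real-data problem in isoform quantification), annotation error,
batch structure beyond what the expression PCs would absorb, or
ancestry-specific effect sizes. Passing recovery tests therefore show
that the statistical machinery is correct under its stated model, not
that isoform quantification from real reads is accurate.

## 7. Problem sizes in the test suite

The suite runs in about two minutes on one CPU: a shared n = 200 fixture
cohort for unit tests; the default n = 1000 cohort for end-to-end
recovery, replication and compositional checks; a 500-sample null cohort
giving >10,000 null tests for type-I calibration (rate at α = 10⁻³
within three binomial standard deviations); 500 neutral-placement
replicates and 50 planted-enrichment seeds for the matched-null engine;
25 fresh 400-sample cohorts × 20 outcome draws (~500 replicates) for IVW
null coverage, judged across cohorts because exposure-side sampling
noise is fixed within any one cohort; and exhaustive enumeration of all
2×2 tables with margins ≤ 30 against a hypergeometric oracle at 1e-12.
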