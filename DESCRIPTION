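Package: irqtl
Title: Isoform-Ratio QTL Mapping on Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maps isoform-ratio quantitative trait loci (irQTLs) from
    transcript-level expression and genotype dosages: FPKM and TMM
    normalization, compositional isoform ratios with explicit missingness,
    additive-dosage cis/trans association scans with genotype and expression
    principal components and family residualization, sentinel selection and
    discovery-to-replication evaluation, matched-null fold enrichment in
    genomic features, GWAS-catalog Fisher enrichment, and two-sample
    Mendelian randomization (IVW and MR-Egger). Includes a synthetic cohort
    generator with planted genotype-dependent isoform usage effects for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    edgeR,
    IRanges,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    lme4,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
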