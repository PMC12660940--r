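#' Read genotype dosages from VCF or a dosage TSV
#'
#' VCF records are read with the DS FORMAT field when present, otherwise
#' hard-called GT genotypes are converted to alternate-allele dosages.
#' Multiallelic records are rejected (the analysis treats every variant as a
#' biallelic dosage). A dosage TSV carries columns \code{id, chrom, pos, ref,
#' alt} followed by one column per sample, with \code{"."} for missing.
#'
#' Per-variant MAF (folded alternate-allele frequency) and Hardy-Weinberg
#' exact-test p-values are computed on read; fractional dosages are rounded
#' to the nearest hard call for the HWE genotype counts only.
#'
#' @param path path to a \code{.vcf} file or a tab-separated dosage matrix.
#' @return a \code{genotype_data} object: list with \code{dosage} (samples x
#'   variants numeric matrix, \code{NA} for missing), \code{variants}
#'   (data.table with id, chrom, pos, ref, alt, maf, hwe_p) and
#'   \code{samples}.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf(\\.gz)?$", path)) {
    gd <- .read_genotypes_vcf(path)
  } else {
    gd <- .read_genotypes_tsv(path)
  }
  gd$variants[, maf := apply(gd$dosage, 2L, compute_maf)]
  gd$variants[, hwe_p := .hwe_from_dosage(gd$dosage)]
  gd
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record(s) rejected: ",
         paste(fix$ID[multi], collapse = ", "))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  has_ds <- all(vapply(strsplit(v@gt[, 1L], ":", fixed = TRUE),
                       function(f) "DS" %in% f, logical(1)))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS")
    dos <- suppressWarnings(matrix(as.numeric(ds), nrow = nrow(ds),
                                   dimnames = dimnames(ds)))
    bad <- !is.na(ds) & is.na(dos)
    if (any(bad)) {
      stop("malformed dosage at variant ",
           ids[which(rowSums(bad) > 0)[1L]])
    }
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- .gt_to_dosage(gt, ids)
  }
  if (any(!is.na(dos) & (dos < 0 | dos > 2))) stop("dosage outside [0, 2]")
  variants <- data.table::data.table(
    id = ids, chrom = .norm_chrom(fix$CHROM), pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, maf = NA_real_, hwe_p = NA_real_)
  dosage <- t(dos)
  colnames(dosage) <- ids
  new_genotype_data(dosage, variants)
}

.gt_to_dosage <- function(gt, ids) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  ok <- grepl("^[01.]([/|][01.])?$", u)
  if (any(!ok)) {
    bad <- which(gt %in% u[!ok], arr.ind = TRUE)[1L, 1L]
    stop("malformed genotype at variant ", ids[bad])
  }
  map <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) NA_real_ else sum(al == "1")
  }, numeric(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out
}

.read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, na.strings = ".", colClasses = list(character = "chrom"))
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(dt))) {
    stop("dosage TSV must carry columns ", paste(meta_cols, collapse = ", "))
  }
  samp <- setdiff(names(dt), meta_cols)
  dos <- as.matrix(dt[, samp, with = FALSE])
  if (!is.numeric(dos)) stop("malformed dosage in TSV (non-numeric sample column)")
  if (any(!is.na(dos) & (dos < 0 | dos > 2))) stop("dosage outside [0, 2]")
  variants <- data.table::data.table(
    id = dt$id, chrom = .norm_chrom(as.character(dt$chrom)), pos = as.integer(dt$pos),
    ref = dt$ref, alt = dt$alt, maf = NA_real_, hwe_p = NA_real_)
  dosage <- t(dos)
  dimnames(dosage) <- list(samp, dt$id)
  new_genotype_data(dosage, variants)
}

#' @keywords internal
new_genotype_data <- function(dosage, variants, family_id = NULL,
                              population = NULL) {
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant id: ", variants$id[duplicated(variants$id)][1L])
  }
  structure(list(dosage = dosage, variants = variants,
                 samples = rownames(dosage), family_id = family_id,
                 population = population),
            class = "genotype_data")
}

.hwe_from_dosage <- function(dosage) {
  apply(dosage, 2L, function(d) {
    d <- round(d[!is.na(d)])
    hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))
  })
}

.norm_chrom <- function(x) sub("^chr", "", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a transcript annotation (GTF or TSV)
#'
#' The TSV form carries columns \code{transcript_id, gene_id, chrom, strand}
#' plus either \code{tss, length} directly or \code{start, end} (1-based,
#' inclusive), from which the TSS is the start coordinate on the + strand and
#' the end coordinate on the - strand. GTF input (transcript and exon
#' features) is read through rtracklayer; exonic length is the summed exon
#' width where exons are present, else the transcript span.
#'
#' @param path annotation file.
#' @return data.table with transcript_id, gene_id, chrom, strand, tss, length.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gtf(\\.gz)?$", path)) {
    ann <- .read_annotation_gtf(path)
  } else {
    ann <- .read_annotation_tsv(path)
  }
  if (anyDuplicated(ann$transcript_id)) {
    stop("duplicate transcript_id: ",
         ann$transcript_id[duplicated(ann$transcript_id)][1L])
  }
  if (any(is.na(ann$gene_id) | ann$gene_id == "")) {
    stop("transcript without gene: ",
         ann$transcript_id[which(is.na(ann$gene_id) | ann$gene_id == "")[1L]])
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("unknown strand for transcript ",
         ann$transcript_id[which(!ann$strand %in% c("+", "-"))[1L]])
  }
  stopifnot(all(ann$length > 0), all(ann$tss >= 1))
  ann[]
}

.read_annotation_tsv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("chrom")))
  req <- c("transcript_id", "gene_id", "chrom", "strand")
  if (!all(req %in% names(dt))) {
    stop("annotation TSV must carry columns ", paste(req, collapse = ", "))
  }
  if (!all(c("tss", "length") %in% names(dt))) {
    if (!all(c("start", "end") %in% names(dt))) {
      stop("annotation TSV needs either tss+length or start+end columns")
    }
    dt[, tss := ifelse(strand == "+", start, end)]
    dt[, length := end - start + 1L]
  }
  data.table::data.table(
    transcript_id = dt$transcript_id, gene_id = dt$gene_id,
    chrom = .norm_chrom(dt$chrom), strand = dt$strand,
    tss = as.integer(dt$tss), length = as.integer(dt$length))
}

.read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GTF input needs the rtracklayer package; use the TSV form instead")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type == "transcript"]
  ex <- gr[gr$type == "exon"]
  exlen <- tapply(BiocGenerics::width(ex), ex$transcript_id, sum)
  strand <- as.character(BiocGenerics::strand(tx))
  len <- exlen[tx$transcript_id]
  len[is.na(len)] <- BiocGenerics::width(tx)[is.na(len)]
  data.table::data.table(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = .norm_chrom(as.character(GenomicRanges::seqnames(tx))),
    strand = strand,
    tss = as.integer(ifelse(strand == "+", BiocGenerics::start(tx),
                            BiocGenerics::end(tx))),
    length = as.integer(len))
}

#' Read a BED3+ feature file into an interval set
#'
#' BED coordinates are 0-based half-open; they are converted to 1-based
#' inclusive intervals on read so that \code{feature_overlap()} queries agree
#' with VCF positions: the BED line \code{chr1 99 100} contains 1-based
#' position 100 only.
#'
#' @param path BED file (>= 3 columns, no header).
#' @return a \code{feature_set} object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(new_feature_set(character(), integer(), integer()))
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  chrom <- .norm_chrom(as.character(dt[[1L]]))
  start0 <- as.integer(dt[[2L]])
  end0 <- as.integer(dt[[3L]])
  bad <- which(start0 >= end0)
  if (length(bad)) stop("BED start >= end at line ", bad[1L])
  new_feature_set(chrom, start0 + 1L, end0)
}

#' @keywords internal
new_feature_set <- function(chrom, start1, end1) {
  sets <- if (length(chrom)) {
    lapply(split(seq_along(chrom), chrom), function(i) {
      IRanges::reduce(IRanges::IRanges(start = start1[i], end = end1[i]))
    })
  } else list()
  structure(list(by_chrom = sets,
                 n_intervals = length(chrom)),
            class = "feature_set")
}

#' Query feature overlap for 1-based positions
#'
#' @param features a \code{feature_set} from [read_bed()].
#' @param chrom,pos parallel vectors of chromosome and 1-based position.
#' @return logical vector: does each position fall inside any interval.
#' @export
feature_overlap <- function(features, chrom, pos) {
  stopifnot(inherits(features, "feature_set"), length(chrom) == length(pos))
  chrom <- .norm_chrom(as.character(chrom))
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    ir <- features$by_chrom[[ch]]
    if (is.null(ir)) next
    i <- which(chrom == ch)
    q <- IRanges::IRanges(start = pos[i], width = 1L)
    out[i] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' Write an association summary TSV
#'
#' Keeps only rows with \code{p < p_threshold} (the storage rule for
#' SNP-isoform pairs), writing columns snp, transcript, gene, chrom, pos,
#' beta, se, p, log10_p, r2, n, relation, distance. Missing values are
#' written as ".".
#'
#' @param records association records (data.table from [scan_irqtl()]).
#' @param path output path.
#' @param p_threshold storage p-value threshold (default 1e-4).
#' @return the path, invisibly.
#' @export
write_summary <- function(records, path, p_threshold = 1e-4) {
  cols <- c("snp", "transcript", "gene", "chrom", "pos", "beta", "se", "p",
            "log10_p", "r2", "n", "relation", "distance")
  keep <- records[p < p_threshold, intersect(cols, names(records)), with = FALSE]
  data.table::fwrite(keep, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Read a summary TSV written by [write_summary()]
#' @param path file path.
#' @return data.table of association records.
#' @export
read_summary <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = ".",
                    colClasses = list(character = intersect(
                      c("chrom"), strsplit(readLines(path, 1L), "\t")[[1L]])))
}
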