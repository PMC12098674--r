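#' Phased cohort genotypes
#'
#' In-memory container for a phased, biallelic SNV cohort. Haplotype 0 is the
#' first allele of the VCF `GT` field, haplotype 1 the second. Missing alleles
#' are `NA`.
#'
#' @param samples character vector of unique sample identifiers.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within a chromosome.
#' @param hap0,hap1 integer matrices (variants x samples) with values 0/1/NA.
#' @return object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(samples, variants, hap0, hap1) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop_validation("duplicate sample id in cohort")
  variants <- as.data.frame(variants)
  variants$chrom <- normalize_chrom(variants$chrom)
  if (!all(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L)) {
    stop_validation("non-SNV variant in cohort_genotypes")
  }
  ord_ok <- all(tapply(variants$pos, variants$chrom,
                       function(p) !is.unsorted(p, strictly = TRUE)))
  if (!isTRUE(ord_ok)) stop_validation("positions not strictly increasing within chromosome")
  hap0 <- as.matrix(hap0); hap1 <- as.matrix(hap1)
  storage.mode(hap0) <- "integer"; storage.mode(hap1) <- "integer"
  if (!all(dim(hap0) == c(nrow(variants), length(samples))) ||
      !all(dim(hap1) == dim(hap0))) {
    stop_validation("haplotype matrix dimensions do not match variants x samples")
  }
  bad <- c(hap0, hap1)
  if (!all(bad %in% c(0L, 1L, NA))) stop_validation("allele values must be 0/1/NA")
  colnames(hap0) <- colnames(hap1) <- samples
  structure(list(samples = samples, variants = variants, hap0 = hap0, hap1 = hap1),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", nrow(x$variants), "variants x", length(x$samples),
      "samples (phased)\n")
  invisible(x)
}

#' Allele dosage matrix
#'
#' @param geno a `cohort_genotypes`.
#' @return integer matrix (variants x samples) of alt-allele dosages 0/1/2,
#'   `NA` when either allele is missing.
#' @export
dosage <- function(geno) {
  stopifnot(inherits(geno, "cohort_genotypes"))
  geno$hap0 + geno$hap1
}

#' Read a phased VCF
#'
#' Retains only phased, biallelic SNV records. Multiallelic, non-SNV and
#' unphased records are skipped and counted in the `skip_report` attribute.
#'
#' @param path VCF file (v4.x, plain text or bgzip).
#' @return `cohort_genotypes` with attribute `skip_report`, a named integer
#'   vector with counts for `multiallelic`, `not_snv`, `unphased`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_cols <- colnames(v@gt)
  if (length(gt_cols) < 2L) stop_format("VCF has no sample columns")
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop_format("VCF record without GT format field")
  samples <- gt_cols[-1]
  if (anyDuplicated(samples)) stop_validation("duplicate sample id in VCF header")
  gt <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, samples))

  multi <- grepl(",", fix[, "ALT"])
  snv <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "REF"] %in% c("A", "C", "G", "T") & fix[, "ALT"] %in% c("A", "C", "G", "T")
  unphased <- apply(gt, 1L, function(g) any(grepl("/", g)))
  keep <- !multi & snv & !unphased
  skip <- c(multiallelic = sum(multi),
            not_snv = sum(!snv & !multi),
            unphased = sum(unphased & snv & !multi))

  gt <- gt[keep, , drop = FALSE]
  a0 <- substr(gt, 1L, 1L)
  a1 <- substr(gt, 3L, 3L)
  to_int <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[a == "0"] <- 0L
    out[a == "1"] <- 1L
    matrix(out, nrow = nrow(gt), dimnames = list(NULL, colnames(gt)))
  }
  variants <- data.frame(chrom = normalize_chrom(fix[keep, "CHROM"]),
                         pos = as.integer(fix[keep, "POS"]),
                         ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                         stringsAsFactors = FALSE)
  out <- cohort_genotypes(samples, variants, to_int(a0), to_int(a1))
  attr(out, "skip_report") <- skip
  out
}

#' Write a phased VCF
#'
#' Plain-text VCF v4.2 with phased GT; deterministic formatting so equal
#' objects produce byte-identical files.
#'
#' @param geno a `cohort_genotypes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "cohort_genotypes"))
  g0 <- geno$hap0; g1 <- geno$hap1
  gt <- matrix(paste0(ifelse(is.na(g0), ".", g0), "|", ifelse(is.na(g1), ".", g1)),
               nrow = nrow(g0))
  body <- paste(geno$variants$chrom, geno$variants$pos, ".",
                geno$variants$ref, geno$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
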