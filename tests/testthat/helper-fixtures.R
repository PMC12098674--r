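# shared fixture builders: everything is generated in code at test time

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# hand-written 2-sample VCF; extra records appended verbatim
tiny_vcf <- function(extra = character()) {
  write_tmp_lines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT", "0|1", "1|1",
          sep = "\t"),
    paste("chr1", "200", ".", "C", "T", ".", "PASS", ".", "GT", "0|0", "0|1",
          sep = "\t"),
    extra))
}

tiny_msp <- function(rows = NULL, codes = "AFR=0\tEUR=1",
                     samples = c("S1", "S2")) {
  if (is.null(rows)) {
    rows <- paste("chr1", "0", "1000000", "0.00", "1.00", "50",
                  "0", "1", "0", "1", sep = "\t")
  }
  hap_cols <- as.vector(rbind(paste0(samples, ".0"), paste0(samples, ".1")))
  write_tmp_lines(c(
    paste0("#Subpopulation order/codes: ", codes),
    paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps", hap_cols),
          collapse = "\t"),
    rows))
}

# two-ancestry local-ancestry object built directly (one chromosome)
make_calls <- function(windows, calls, samples,
                       codes = c(AFR = 0L, EUR = 1L)) {
  colnames(calls) <- as.vector(rbind(paste0(samples, ".0"),
                                     paste0(samples, ".1")))
  local_ancestry(codes, windows, calls)
}

linear_map <- function(chroms = "chr1", bp = 1e7, cm = 100) {
  genetic_map(do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(chrom = chroms[i], pos = c(0, bp), cM = c(0, cm))
  })))
}

# desk-scale two-ancestry config for generator tests
two_anc_config <- function(...) {
  sim_config(labels = c("A", "B"),
             subcohorts = list(list(weight = 1, alpha = c(A = 2, B = 2))),
             chrom = data.frame(chrom = "chr1", bp = 1e7, cM = 100),
             catalog_model = c(A = 0.99, B = 0.80),
             relatives = c(), ...)
}

# genotypes object from explicit haplotype matrices
make_geno <- function(hap0, hap1, samples = paste0("S", seq_len(ncol(hap0))),
                      chrom = "chr1") {
  nv <- nrow(hap0)
  cohort_genotypes(samples,
                   data.frame(chrom = chrom, pos = seq_len(nv) * 1000L,
                              ref = "A", alt = "G"),
                   hap0, hap1)
}

# independent scalar re-statement of the printed categorisation rules, used
# as the brute-force oracle for classify_ancestry
classify_oracle <- function(p, labels,
                            named_pairs = c("EUR-AFR", "EUR-AMR")) {
  if (any(p > 0.85)) return(labels[which.max(p)])
  ord <- order(p, decreasing = TRUE)
  top2 <- ord[1:2]
  if (all(p[top2] >= 0.15) && sum(p[top2]) > 0.85) {
    ab <- sort(labels[top2])
    lab <- paste(ab, collapse = "-")
    for (np in named_pairs) {
      if (identical(sort(strsplit(np, "-")[[1]]), ab)) return(np)
    }
    return(lab)
  }
  if (sum(p > 0.15) >= 3) return("MULTIWAY")
  "UNASSIGNED"
}
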