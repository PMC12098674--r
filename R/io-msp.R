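#' Local ancestry calls
#'
#' Container for window-based local-ancestry calls in the RFMix2 `msp.tsv`
#' layout: windows are half-open bp intervals `[spos, epos)` shared by all
#' haplotypes, each haplotype column carrying one ancestry code per window.
#'
#' @param codes named integer vector mapping ancestry label to integer code.
#' @param windows data.frame with columns `chrom`, `spos`, `epos`, `sgpos`,
#'   `egpos`, `n_snps`; non-overlapping and sorted within chromosome.
#' @param calls integer matrix (windows x haplotypes); column names must be
#'   `<sample>.0` / `<sample>.1` pairs.
#' @return object of class `local_ancestry`.
#' @export
local_ancestry <- function(codes, windows, calls) {
  if (is.null(names(codes)) || anyDuplicated(names(codes)) || anyDuplicated(codes)) {
    stop_validation("ancestry codes must be a uniquely named label->integer map")
  }
  codes <- setNames(as.integer(codes), names(codes))
  windows <- as.data.frame(windows)
  windows$chrom <- normalize_chrom(windows$chrom)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(windows)) stop_validation("calls rows != windows rows")
  cols <- colnames(calls)
  if (is.null(cols) || !all(grepl("\\.[01]$", cols))) {
    stop_validation("haplotype columns must be named <sample>.0 / <sample>.1")
  }
  samples <- unique(sub("\\.[01]$", "", cols))
  want <- as.vector(rbind(paste0(samples, ".0"), paste0(samples, ".1")))
  if (!setequal(cols, want) || length(cols) != length(want)) {
    stop_validation("haplotype column without matching .0/.1 pair")
  }
  calls <- calls[, want, drop = FALSE]
  if (!all(calls %in% codes)) stop_validation("unknown ancestry code in calls")
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    if (any(w$spos >= w$epos)) stop_validation("window with spos >= epos on ", ch)
    if (is.unsorted(w$spos, strictly = TRUE) || any(head(w$epos, -1) > tail(w$spos, -1))) {
      stop_validation("overlapping or unsorted windows on ", ch)
    }
  }
  structure(list(codes = codes, windows = windows, calls = calls, samples = samples),
            class = "local_ancestry")
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat("local_ancestry:", nrow(x$windows), "windows,", length(x$samples),
      "samples,", length(x$codes), "ancestries (",
      paste(names(x$codes), collapse = ", "), ")\n")
  invisible(x)
}

#' Read RFMix2-style msp.tsv local ancestry calls
#'
#' Expects the two-line header dialect: line 1
#' `#Subpopulation order/codes: LABEL=0<tab>LABEL=1...`, line 2 the column
#' header starting `#chm`. Accepts one file covering one or several
#' chromosomes.
#'
#' @param path msp.tsv file.
#' @return a `local_ancestry`.
#' @export
read_msp <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !startsWith(hdr[1], "#Subpopulation order/codes:")) {
    stop_format("msp file must start with '#Subpopulation order/codes:'")
  }
  tok <- regmatches(hdr[1], gregexpr("[A-Za-z0-9_]+=[0-9]+", hdr[1]))[[1]]
  if (length(tok) == 0) stop_format("no LABEL=code pairs in msp header")
  parts <- strsplit(tok, "=", fixed = TRUE)
  codes <- setNames(as.integer(vapply(parts, `[`, "", 2L)),
                    vapply(parts, `[`, "", 1L))
  cols <- strsplit(sub("^#", "", hdr[2]), "\t")[[1]]
  if (length(cols) < 7L || cols[1] != "chm") stop_format("unexpected msp column header")
  body <- data.table::fread(path, skip = 2L, header = FALSE, sep = "\t",
                            colClasses = list(character = 1L))
  if (ncol(body) != length(cols)) stop_format("msp body/header column mismatch")
  windows <- data.frame(chrom = normalize_chrom(body[[1]]),
                        spos = as.integer(body[[2]]), epos = as.integer(body[[3]]),
                        sgpos = as.numeric(body[[4]]), egpos = as.numeric(body[[5]]),
                        n_snps = as.integer(body[[6]]))
  calls <- as.matrix(body[, -(1:6)])
  colnames(calls) <- cols[-(1:6)]
  local_ancestry(codes, windows, calls)
}

#' Write msp.tsv local ancestry calls
#'
#' @param la a `local_ancestry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(la, path) {
  stopifnot(inherits(la, "local_ancestry"))
  l1 <- paste0("#Subpopulation order/codes: ",
               paste0(names(la$codes), "=", la$codes, collapse = "\t"))
  l2 <- paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                colnames(la$calls)), collapse = "\t")
  w <- la$windows
  body <- paste(w$chrom, w$spos, w$epos,
                formatC(w$sgpos, format = "f", digits = 2),
                formatC(w$egpos, format = "f", digits = 2),
                w$n_snps,
                apply(la$calls, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(l1, l2, body), path)
  invisible(path)
}
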