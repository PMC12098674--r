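IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Read a genetic map TSV
#'
#' Layout: tab-separated with header `chrom  pos  cM`.
#'
#' @param path file path.
#' @return a `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1L))
  if (!all(c("chrom", "pos", "cM") %in% names(d))) {
    stop_format("genetic map TSV needs header: chrom pos cM")
  }
  genetic_map(as.data.frame(d))
}

#' @rdname read_genetic_map
#' @param map a `genetic_map` (anchor-based).
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"), !is.null(map$anchors))
  rows <- data.table::rbindlist(lapply(names(map$anchors), function(ch) {
    data.table::data.table(chrom = ch, pos = map$anchors[[ch]]$pos,
                           cM = formatC(map$anchors[[ch]]$cM, format = "f", digits = 6))
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' Read variant annotations
#'
#' Layout: TSV `chrom pos ref alt impact consequence sift polyphen known`.
#' `impact` must be one of HIGH/MODERATE/LOW/MODIFIER; `sift`/`polyphen` may
#' be `NA` (missing scores are retained as missing, never coerced to 0);
#' `known` is `true`/`false` catalog membership.
#'
#' @param path file path.
#' @return data.frame of class `variant_annotations`.
#' @export
read_annotations <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       colClasses = list(character = 1L),
                                       na.strings = c("NA", ".")))
  validate_annotations(d)
}

#' @rdname read_annotations
#' @param ann a `variant_annotations` data.frame.
#' @export
write_annotations <- function(ann, path) {
  out <- as.data.frame(ann)
  out$known <- ifelse(out$known, "true", "false")
  out$sift <- ifelse(is.na(out$sift), "NA", formatC(out$sift, format = "f", digits = 4))
  out$polyphen <- ifelse(is.na(out$polyphen), "NA",
                         formatC(out$polyphen, format = "f", digits = 4))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

validate_annotations <- function(d) {
  need <- c("chrom", "pos", "ref", "alt", "impact", "consequence", "sift",
            "polyphen", "known")
  if (!all(need %in% names(d))) {
    stop_format("annotation TSV needs columns: ", paste(need, collapse = " "))
  }
  d$chrom <- normalize_chrom(d$chrom)
  d$pos <- as.integer(d$pos)
  if (anyNA(d$impact) || !all(d$impact %in% IMPACT_LEVELS)) {
    stop_validation("impact must always be one of ", paste(IMPACT_LEVELS, collapse = "/"))
  }
  d$sift <- as.numeric(d$sift)
  d$polyphen <- as.numeric(d$polyphen)
  for (sc in c("sift", "polyphen")) {
    v <- d[[sc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop_validation(sc, " score out of [0,1]")
  }
  if (is.character(d$known)) d$known <- tolower(d$known) == "true"
  d$known <- as.logical(d$known)
  if (anyNA(d$known)) stop_validation("known flag must be true/false")
  class(d) <- c("variant_annotations", "data.frame")
  d
}

#' Read sample metadata
#'
#' Wide layout: TSV `sample race zone age` followed by one column per
#' condition with values `case`/`control`/`NA`.
#'
#' @param path file path.
#' @return data.frame of class `sample_metadata` with attribute `conditions`
#'   (the phenotype column names).
#' @export
read_metadata <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       na.strings = c("NA", "")))
  validate_metadata(d)
}

#' @rdname read_metadata
#' @param meta a `sample_metadata` data.frame.
#' @export
write_metadata <- function(meta, path) {
  data.table::fwrite(as.data.frame(meta), path, sep = "\t")
  invisible(path)
}

validate_metadata <- function(d) {
  need <- c("sample", "race", "zone", "age")
  if (!all(need %in% names(d))) {
    stop_format("metadata TSV needs columns: ", paste(need, collapse = " "))
  }
  if (anyDuplicated(d$sample)) stop_validation("duplicate sample id in metadata")
  conds <- setdiff(names(d), need)
  for (cn in conds) {
    v <- d[[cn]]
    if (!all(is.na(v) | v %in% c("case", "control"))) {
      stop_validation("phenotype column ", cn, " has values outside case/control/NA")
    }
  }
  attr(d, "conditions") <- conds
  class(d) <- c("sample_metadata", "data.frame")
  d
}

#' Read IBD segments (hap-ibd output layout)
#'
#' Layout: TSV `sample1 hap1 sample2 hap2 chrom start end cM` with haplotype
#' indices in {1,2} and half-open bp intervals `[start, end)`. Pairs are
#' stored in canonical order (smaller sample id first).
#'
#' @param path file path.
#' @return data.frame of class `ibd_segments`.
#' @export
read_ibd <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_ibd(d)
}

#' @rdname read_ibd
#' @param ibd an `ibd_segments` data.frame.
#' @export
write_ibd <- function(ibd, path) {
  out <- as.data.frame(ibd)
  out$cM <- formatC(out$cM, format = "f", digits = 4)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

validate_ibd <- function(d) {
  need <- c("sample1", "hap1", "sample2", "hap2", "chrom", "start", "end", "cM")
  if (!all(need %in% names(d))) {
    stop_format("IBD TSV needs columns: ", paste(need, collapse = " "))
  }
  d$chrom <- normalize_chrom(d$chrom)
  if (any(d$start >= d$end)) stop_validation("IBD segment with start >= end")
  if (any(d$cM < 0)) stop_validation("negative IBD segment cM length")
  if (!all(d$hap1 %in% 1:2 & d$hap2 %in% 1:2)) stop_validation("haplotype index must be 1 or 2")
  swap <- d$sample1 > d$sample2
  if (any(swap)) {
    tmp_s <- d$sample1[swap]; tmp_h <- d$hap1[swap]
    d$sample1[swap] <- d$sample2[swap]; d$hap1[swap] <- d$hap2[swap]
    d$sample2[swap] <- tmp_s; d$hap2[swap] <- tmp_h
  }
  d <- d[order(d$sample1, d$sample2, d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("ibd_segments", "data.frame")
  d
}
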