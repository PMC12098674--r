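#' Variant flagging rules
#'
#' Defaults follow the published definitions: rare = cohort alternate-allele
#' frequency below 1%; deleterious = HIGH impact, or missense with
#' SIFT < 0.05 and PolyPhen > 0.85 (PolyPhen oriented higher = more
#' damaging); synonymous by consequence; novel = absent from reference
#' catalogs (`known = FALSE`).
#'
#' @param rare_af_max rare-variant AF threshold (strict `<`, default 0.01).
#' @param sift_max SIFT damaging threshold (strict `<`, default 0.05).
#' @param polyphen_min PolyPhen damaging threshold (strict `>`, default 0.85).
#' @return object of class `variant_flag_rules`.
#' @export
variant_flag_rules <- function(rare_af_max = 0.01, sift_max = 0.05,
                               polyphen_min = 0.85) {
  for (v in c(rare_af_max, sift_max, polyphen_min)) {
    if (!(v > 0 && v < 1)) stop_validation("flag thresholds must lie in (0,1)")
  }
  structure(list(rare_af_max = rare_af_max, sift_max = sift_max,
                 polyphen_min = polyphen_min), class = "variant_flag_rules")
}

#' Cohort alternate-allele frequency
#'
#' `AF = alt allele count / number of non-missing alleles` per variant;
#' missing alleles are excluded from the denominator. Sites where every
#' allele is missing get `NA`.
#'
#' @param geno a `cohort_genotypes`.
#' @return numeric vector of per-variant frequencies.
#' @export
cohort_af <- function(geno) {
  stopifnot(inherits(geno, "cohort_genotypes"))
  alt <- rowSums(geno$hap0, na.rm = TRUE) + rowSums(geno$hap1, na.rm = TRUE)
  nn <- rowSums(!is.na(geno$hap0)) + rowSums(!is.na(geno$hap1))
  af <- ifelse(nn > 0, alt / nn, NA_real_)
  af
}

#' Per-variant boolean flags
#'
#' @param geno a `cohort_genotypes` (used for the cohort AF).
#' @param annotations a `variant_annotations` aligned to `geno$variants`
#'   (matched on chrom/pos/ref/alt).
#' @param rules a `variant_flag_rules`.
#' @return data.frame with columns `af`, `rare`, `deleterious`, `synonymous`,
#'   `novel`, one row per variant in `geno`.
#' @export
variant_flags <- function(geno, annotations, rules = variant_flag_rules()) {
  ann <- align_annotations(geno, annotations)
  af <- cohort_af(geno)
  missense <- grepl("missense", ann$consequence, fixed = TRUE)
  deleterious <- ann$impact == "HIGH" |
    (missense & !is.na(ann$sift) & !is.na(ann$polyphen) &
       ann$sift < rules$sift_max & ann$polyphen > rules$polyphen_min)
  data.frame(af = af,
             rare = !is.na(af) & af < rules$rare_af_max,
             deleterious = deleterious,
             synonymous = grepl("synonymous", ann$consequence, fixed = TRUE),
             novel = !ann$known)
}

# match annotation rows to cohort variants; every cohort variant must be
# annotated (impact is mandatory)
align_annotations <- function(geno, annotations) {
  key <- function(d) paste(normalize_chrom(d$chrom), d$pos, d$ref, d$alt)
  idx <- match(key(geno$variants), key(annotations))
  if (anyNA(idx)) stop_validation("annotations missing for ", sum(is.na(idx)), " variants")
  annotations[idx, , drop = FALSE]
}

#' Assign each alternate allele to the ancestry of its covering tract
#'
#' For every alt allele at `(chrom, pos)` on haplotype `h`, the covering
#' local-ancestry window (half-open, `spos <= pos-1 < epos`) determines the
#' ancestry; positions outside all windows are labelled `UNKNOWN` and counted
#' in the `coverage_report` attribute.
#'
#' @param geno a `cohort_genotypes`.
#' @param calls a `local_ancestry` covering the same samples.
#' @return data.frame with columns `variant` (row index in `geno$variants`),
#'   `sample`, `hap` (0/1), `ancestry`; attribute `coverage_report` holds the
#'   count of unassigned alleles.
#' @export
assign_alleles <- function(geno, calls) {
  stopifnot(inherits(geno, "cohort_genotypes"), inherits(calls, "local_ancestry"))
  missing_s <- setdiff(geno$samples, calls$samples)
  if (length(missing_s)) {
    stop_validation("samples absent from local-ancestry calls: ",
                    paste(head(missing_s, 5), collapse = ", "))
  }
  code_to_label <- setNames(names(calls$codes), calls$codes)
  # window index per variant (NA when uncovered)
  widx <- rep(NA_integer_, nrow(geno$variants))
  for (ch in unique(geno$variants$chrom)) {
    wsel <- which(calls$windows$chrom == ch)
    vsel <- which(geno$variants$chrom == ch)
    if (length(wsel) == 0) next
    w <- calls$windows[wsel, ]
    p0 <- geno$variants$pos[vsel] - 1L
    i <- findInterval(p0, w$spos)
    ok <- i >= 1L & p0 < w$epos[pmax(i, 1L)]
    widx[vsel[ok]] <- wsel[i[ok]]
  }
  out <- list()
  for (h in 0:1) {
    mat <- if (h == 0) geno$hap0 else geno$hap1
    carriers <- which(mat == 1L, arr.ind = TRUE)
    if (nrow(carriers) == 0) next
    v <- carriers[, 1]
    s <- geno$samples[carriers[, 2]]
    wcol <- match(paste0(s, ".", h), colnames(calls$calls))
    wi <- widx[v]
    anc <- rep("UNKNOWN", length(v))
    cov <- !is.na(wi)
    anc[cov] <- code_to_label[as.character(calls$calls[cbind(wi[cov], wcol[cov])])]
    out[[h + 1]] <- data.frame(variant = v, sample = s, hap = h, ancestry = anc)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(variant = integer(), sample = character(), hap = integer(),
               ancestry = character())
  }
  res <- res[order(res$variant, res$sample, res$hap), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "coverage_report") <- c(unknown = sum(res$ancestry == "UNKNOWN"),
                                    assigned = sum(res$ancestry != "UNKNOWN"))
  res
}

#' Tract length (bp) per sample and ancestry
#'
#' Summed over both haplotypes.
#'
#' @param calls a `local_ancestry`.
#' @return numeric matrix (samples x ancestry labels) of bp.
#' @export
tract_bp <- function(calls) {
  w <- as.numeric(calls$windows$epos - calls$windows$spos)
  labels <- names(sort(calls$codes))
  hap_tot <- matrix(0, nrow = length(labels), ncol = ncol(calls$calls),
                    dimnames = list(labels, colnames(calls$calls)))
  for (k in labels) {
    hap_tot[k, ] <- colSums(w * (calls$calls == calls$codes[[k]]))
  }
  n <- length(calls$samples)
  out <- t(hap_tot[, 2 * seq_len(n) - 1, drop = FALSE] +
             hap_tot[, 2 * seq_len(n), drop = FALSE])
  rownames(out) <- calls$samples
  out
}

#' Rare deleterious / synonymous burden by ancestry segment
#'
#' Allele-level counting: each rare deleterious or rare synonymous alt allele
#' increments the count of its assigned ancestry for its carrier (homozygous
#' alt contributes 2). Rates are per Gb of diploid tract length.
#'
#' @param assignment output of [assign_alleles()].
#' @param flags output of [variant_flags()].
#' @param calls a `local_ancestry` (for tract lengths).
#' @return data.frame with one row per sample x ancestry: counts, `tract_bp`,
#'   `per_gb_deleterious`, `del_syn_ratio` (`NA` when the synonymous count is
#'   zero). `UNKNOWN`-assigned alleles appear with zero tract length.
#' @export
burden_by_ancestry <- function(assignment, flags, calls) {
  tbp <- tract_bp(calls)
  labels <- colnames(tbp)
  samples <- rownames(tbp)
  rare_del <- flags$rare & flags$deleterious
  rare_syn <- flags$rare & flags$synonymous
  grid <- expand.grid(sample = samples, ancestry = c(labels, "UNKNOWN"),
                      stringsAsFactors = FALSE)
  count_by <- function(keep) {
    sel <- assignment[keep[assignment$variant], , drop = FALSE]
    if (nrow(sel) == 0) return(rep(0L, nrow(grid)))
    tb <- table(paste(sel$sample, sel$ancestry, sep = "\r"))
    out <- as.integer(tb[paste(grid$sample, grid$ancestry, sep = "\r")])
    ifelse(is.na(out), 0L, out)
  }
  grid$n_rare_deleterious <- count_by(rare_del)
  grid$n_rare_synonymous <- count_by(rare_syn)
  grid$tract_bp <- 0
  known_rows <- grid$ancestry != "UNKNOWN"
  grid$tract_bp[known_rows] <- tbp[cbind(grid$sample[known_rows],
                                         grid$ancestry[known_rows])]
  grid$per_gb_deleterious <- ifelse(grid$tract_bp > 0,
                                    grid$n_rare_deleterious / (grid$tract_bp / 1e9),
                                    NA_real_)
  grid$del_syn_ratio <- ifelse(grid$n_rare_synonymous > 0,
                               grid$n_rare_deleterious / grid$n_rare_synonymous,
                               NA_real_)
  grid[order(grid$sample, grid$ancestry), , drop = FALSE]
}

#' Per-variant private-to-ancestry labels
#'
#' A variant is private to an ancestry when every carrier allele in the
#' cohort is assigned to that single ancestry.
#'
#' @param assignment output of [assign_alleles()].
#' @param n_variants total variant count (labels returned for all variants).
#' @return character vector: the ancestry label for private variants, `NA`
#'   for shared/uncarried/partially-unassigned variants.
#' @export
private_to_ancestry <- function(assignment, n_variants) {
  out <- rep(NA_character_, n_variants)
  if (nrow(assignment) == 0) return(out)
  anc_by_var <- split(assignment$ancestry, assignment$variant)
  uni <- vapply(anc_by_var, function(a) {
    u <- unique(a)
    if (length(u) == 1L && u != "UNKNOWN") u else NA_character_
  }, "")
  out[as.integer(names(anc_by_var))] <- uni
  out
}

#' Novel-variant counts per individual, grouped by ancestry category
#'
#' Variant-level counting: the number of distinct novel (and rare novel)
#' variants an individual carries. In per-tract mode, admixed individuals are
#' replicated once per ancestry contributing at least `component_min` of the
#' genome, counting only novel variants with at least one allele assigned to
#' that ancestry (the published "represented twice" convention).
#'
#' @param geno a `cohort_genotypes`.
#' @param flags output of [variant_flags()].
#' @param categories named sample->category vector.
#' @param per_tract replicate individuals per ancestry component.
#' @param assignment required when `per_tract = TRUE`; output of
#'   [assign_alleles()].
#' @param proportions required when `per_tract = TRUE`; matrix from
#'   [global_from_tracts()].
#' @param component_min per-ancestry replication threshold (default 0.15).
#' @return data.frame with columns `sample`, `group`, `n_novel`,
#'   `n_novel_rare`.
#' @export
novelty_by_group <- function(geno, flags, categories, per_tract = FALSE,
                             assignment = NULL, proportions = NULL,
                             component_min = 0.15) {
  ds <- dosage(geno)
  carried <- !is.na(ds) & ds > 0
  if (!per_tract) {
    n_novel <- colSums(carried & flags$novel)
    n_rare <- colSums(carried & flags$novel & flags$rare)
    return(data.frame(sample = geno$samples,
                      group = unname(categories[geno$samples]),
                      n_novel = as.integer(n_novel),
                      n_novel_rare = as.integer(n_rare)))
  }
  if (is.null(assignment) || is.null(proportions)) {
    stop_validation("per-tract novelty needs assignment and proportions")
  }
  novel_assign <- assignment[flags$novel[assignment$variant] &
                               assignment$ancestry != "UNKNOWN", , drop = FALSE]
  rare_flag <- flags$rare[novel_assign$variant]
  out <- list()
  for (s in geno$samples) {
    ancs <- colnames(proportions)[proportions[s, ] >= component_min]
    sel <- novel_assign[novel_assign$sample == s, , drop = FALSE]
    sel_rare <- rare_flag[novel_assign$sample == s]
    for (a in ancs) {
      in_a <- sel$ancestry == a
      out[[length(out) + 1]] <- data.frame(
        sample = s, group = a,
        n_novel = length(unique(sel$variant[in_a])),
        n_novel_rare = length(unique(sel$variant[in_a & sel_rare])))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Novel-vs-known impact enrichment (closed-form logistic coefficients)
#'
#' For each impact category against the MODIFIER reference, the log odds
#' ratio of being novel: `beta = log[(novel_c/known_c) / (novel_ref/known_ref)]`
#' with `se = sqrt(sum of reciprocal cells)` — the exact maximum-likelihood
#' estimate of a logistic regression of novelty on impact category. A
#' Haldane-Anscombe 0.5 is added to all four cells when any is zero.
#'
#' @param flags output of [variant_flags()] (uses `novel`).
#' @param annotations aligned `variant_annotations` (uses `impact`).
#' @param reference reference impact level (default `"MODIFIER"`).
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per non-reference impact category:
#'   `beta`, `se`, `ci_low`, `ci_high`, the four cell counts, `corrected`.
#' @export
impact_enrichment <- function(flags, annotations, reference = "MODIFIER",
                              conf = 0.95) {
  impact <- annotations$impact
  novel <- flags$novel
  if (!any(impact == reference)) {
    stop_validation("no variants in reference impact category ", reference)
  }
  novel_ref <- sum(novel & impact == reference)
  known_ref <- sum(!novel & impact == reference)
  cats <- setdiff(IMPACT_LEVELS, reference)
  z <- qnorm(1 - (1 - conf) / 2)
  rows <- lapply(cats, function(cc) {
    novel_c <- sum(novel & impact == cc)
    known_c <- sum(!novel & impact == cc)
    if (novel_c + known_c == 0) {
      return(data.frame(impact = cc, beta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        novel_c = 0L, known_c = 0L,
                        novel_ref = novel_ref, known_ref = known_ref,
                        corrected = NA))
    }
    cells <- c(novel_c, known_c, novel_ref, known_ref)
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    beta <- log(cells[1] / cells[2]) - log(cells[3] / cells[4])
    se <- sqrt(sum(1 / cells))
    data.frame(impact = cc, beta = beta, se = se,
               ci_low = beta - z * se, ci_high = beta + z * se,
               novel_c = novel_c, known_c = known_c,
               novel_ref = novel_ref, known_ref = known_ref,
               corrected = corrected)
  })
  do.call(rbind, rows)
}
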