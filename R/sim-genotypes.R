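#' Simulate variant positions, annotations and ancestry-specific frequencies
#'
#' Positions are drawn uniformly (without replacement) per chromosome in
#' proportion to bp length. Impact classes follow the configured
#' probabilities; missense variants get SIFT/PolyPhen scores from the
#' configured Beta samplers. Each variant gets one frequency per ancestry
#' (functional classes use the low-frequency Beta, MODIFIER the common one);
#' its origin ancestry is the argmax frequency (ties to the lowest code) and
#' catalog membership is Bernoulli in the origin's catalog completeness.
#'
#' @param config a `sim_config`.
#' @return list with `variants` (chrom/pos/ref/alt), `annotations`
#'   (a `variant_annotations`), `freqs` (variants x K matrix), `origin`
#'   (integer ancestry codes) and `deleterious` (the generative deleterious
#'   indicator).
#' @export
simulate_variants <- function(config) {
  n_per <- round(config$n_variants * config$chrom$bp / sum(config$chrom$bp))
  n_per[1] <- config$n_variants - sum(n_per[-1])
  pos_l <- lapply(seq_len(nrow(config$chrom)), function(ci) {
    sort(sample.int(config$chrom$bp[ci], n_per[ci]))
  })
  variants <- data.frame(
    chrom = rep(config$chrom$chrom, n_per),
    pos = as.integer(unlist(pos_l)))
  nv <- nrow(variants)
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, nv, replace = TRUE)
  alt_off <- sample.int(3L, nv, replace = TRUE)
  variants$alt <- bases[(match(variants$ref, bases) - 1L + alt_off) %% 4L + 1L]

  am <- config$annotation_model
  impact <- sample(names(am$impact_probs), nv, replace = TRUE,
                   prob = am$impact_probs)
  consequence <- c(HIGH = "stop_gained", MODERATE = "missense_variant",
                   LOW = "synonymous_variant", MODIFIER = "intron_variant")[impact]
  sift <- rep(NA_real_, nv)
  polyphen <- rep(NA_real_, nv)
  mis <- impact == "MODERATE"
  sift[mis] <- rbeta(sum(mis), am$sift[1], am$sift[2])
  polyphen[mis] <- rbeta(sum(mis), am$polyphen[1], am$polyphen[2])

  deleterious <- impact == "HIGH" |
    (mis & !is.na(sift) & sift < 0.05 & !is.na(polyphen) & polyphen > 0.85)

  fm <- config$freq_model
  functional <- impact != "MODIFIER"
  freqs <- matrix(0, nv, config$K, dimnames = list(NULL, config$labels))
  if (isTRUE(fm$shared)) {
    # homogeneous null model: one frequency per variant for every ancestry
    f <- numeric(nv)
    f[functional] <- rbeta(sum(functional), fm$functional[1], fm$functional[2])
    f[!functional] <- rbeta(sum(!functional), fm$modifier[1], fm$modifier[2])
    freqs[] <- f
  } else {
    for (k in seq_len(config$K)) {
      freqs[functional, k] <- rbeta(sum(functional), fm$functional[1], fm$functional[2])
      freqs[!functional, k] <- rbeta(sum(!functional), fm$modifier[1], fm$modifier[2])
    }
  }
  dr <- fm$deleterious_ratio
  if (!is.null(dr)) {
    sel <- deleterious
    freqs[sel, dr$num] <- pmin(dr$ratio * freqs[sel, dr$den], 1)
  }
  origin <- max.col(freqs, ties.method = "first") - 1L
  known <- runif(nv) < config$catalog_model[origin + 1L]

  ann <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    impact = unname(impact), consequence = unname(consequence),
                    sift = sift, polyphen = polyphen, known = known)
  list(variants = variants, annotations = validate_annotations(ann),
       freqs = freqs, origin = origin, deleterious = deleterious)
}

# draw alleles for every founder haplotype: Bernoulli in the frequency of the
# ancestry covering each variant position
founder_hap_alleles <- function(founder_tracts, variants, freqs) {
  ids <- names(founder_tracts)
  out <- matrix(0L, nrow(variants), length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    anc <- tract_anc_at(founder_tracts[[id]], variants$chrom, variants$pos)
    p <- freqs[cbind(seq_len(nrow(variants)), anc + 1L)]
    out[, id] <- as.integer(runif(nrow(variants)) < p)
  }
  out
}

# alleles of one (possibly mosaic) haplotype via founder-source lookup
hap_alleles <- function(hap_segs, variants, founder_alleles) {
  out <- rep(NA_integer_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    segs <- hap_segs[hap_segs$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    sel <- which(variants$chrom == ch)
    p0 <- variants$pos[sel] - 1L
    i <- findInterval(p0, segs$start)
    src <- segs$src[i]
    out[sel] <- founder_alleles[cbind(sel, match(as.character(src),
                                                 colnames(founder_alleles)))]
  }
  out
}

#' Simulate phased genotypes for a set of simulated individuals
#'
#' Materialises alleles for every individual in a [simulate_relatives()]
#' structure: founder haplotypes draw Bernoulli alleles in the frequency of
#' the ancestry tract covering each position; descendant haplotypes inherit
#' the founder alleles through their recombination mosaics.
#'
#' @param rel a [simulate_relatives()] result.
#' @param sample_ids which individuals to include (default: all).
#' @param variants a [simulate_variants()] result.
#' @return a `cohort_genotypes`.
#' @export
simulate_genotypes <- function(rel, variants, sample_ids = NULL) {
  ids <- sample_ids %||% names(rel$individuals)
  fa <- founder_hap_alleles(rel$founder_tracts, variants$variants, variants$freqs)
  nv <- nrow(variants$variants)
  hap0 <- matrix(0L, nv, length(ids), dimnames = list(NULL, ids))
  hap1 <- hap0
  for (s in seq_along(ids)) {
    ind <- rel$individuals[[ids[s]]]
    hap0[, s] <- hap_alleles(ind$hap1, variants$variants, fa)
    hap1[, s] <- hap_alleles(ind$hap2, variants$variants, fa)
  }
  cohort_genotypes(ids, variants$variants, hap0, hap1)
}
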