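#' IBD segment merge parameters
#'
#' Defaults follow the published post-processing: gaps shorter than 0.6 cM
#' containing at most one discordant homozygote are closed.
#'
#' @param max_gap_cM maximum gap to close (strict `<`, default 0.6).
#' @param max_discordant_homozygotes maximum opposite-homozygote sites inside
#'   a closed gap (default 1).
#' @param min_seed_cM detection seed length the input segments were called
#'   with (default 2.0; informational).
#' @return object of class `ibd_merge_params`.
#' @export
ibd_merge_params <- function(max_gap_cM = 0.6, max_discordant_homozygotes = 1L,
                             min_seed_cM = 2.0) {
  if (max_gap_cM <= 0 || max_discordant_homozygotes < 0 || min_seed_cM <= 0) {
    stop_validation("IBD merge parameters must be positive")
  }
  structure(list(max_gap_cM = max_gap_cM,
                 max_discordant_homozygotes = as.integer(max_discordant_homozygotes),
                 min_seed_cM = min_seed_cM), class = "ibd_merge_params")
}

#' Relationship-degree bins on the kinship coefficient
#'
#' Standard powers-of-two bins: kinship above `2^-1.5/2` (0.3536) is a
#' duplicate/monozygotic pair, then first, second and third degree down to
#' the 0.0442 unrelated cutoff; 0.0884 is the published second-degree
#' boundary.
#'
#' @param cuts decreasing numeric vector of bin edges.
#' @param labels labels for `(cuts[k+1], cuts[k]]` bins plus the final
#'   unrelated class.
#' @return object of class `degree_bins`.
#' @export
degree_bins <- function(cuts = c(0.3536, 0.1768, 0.0884, 0.0442),
                        labels = c("duplicate", "first", "second", "third",
                                   "unrelated")) {
  if (is.unsorted(rev(cuts), strictly = TRUE)) {
    stop_validation("degree cutpoints must be strictly decreasing")
  }
  if (length(labels) != length(cuts) + 1L) stop_validation("need one label per bin")
  structure(list(cuts = cuts, labels = labels), class = "degree_bins")
}

#' KING-robust kinship coefficient for one pair
#'
#' `phi = (N_AaAa - 2 N_AAaa) / (N_Aa_i + N_Aa_j)` over sites where both
#' individuals are genotyped and the cohort minor-allele frequency exceeds
#' `maf_min`. Robust to population structure because the denominator uses
#' only the pair's own heterozygosity.
#'
#' @param geno a `cohort_genotypes`.
#' @param i,j sample identifiers.
#' @param maf_min cohort MAF filter (strict `>`, default 0.01).
#' @param sites optional variant index vector (e.g. an LD-pruned site list)
#'   applied before the MAF filter.
#' @return list with `phi`, `n_sites`, and the four counts; `phi` is `NA`
#'   (flagged `defined = FALSE`) when the denominator is zero.
#' @export
king_robust <- function(geno, i, j, maf_min = 0.01, sites = NULL) {
  ds <- dosage(geno)
  gi <- ds[, i]; gj <- ds[, j]
  af <- cohort_af(geno)
  maf <- pmin(af, 1 - af)
  use <- !is.na(gi) & !is.na(gj) & !is.na(maf) & maf > maf_min
  if (!is.null(sites)) use <- use & seq_along(gi) %in% sites
  gi <- gi[use]; gj <- gj[use]
  n_aa <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  het_i <- sum(gi == 1L)
  het_j <- sum(gj == 1L)
  denom <- het_i + het_j
  phi <- if (denom > 0) (n_aa - 2 * n_opp) / denom else NA_real_
  list(phi = phi, n_sites = sum(use), n_AaAa = n_aa, n_AAaa = n_opp,
       n_Aa_i = het_i, n_Aa_j = het_j, defined = denom > 0)
}

#' KING-robust kinship for all sample pairs
#'
#' Matrix-algebra implementation of [king_robust()] over every pair; missing
#' genotypes are excluded pairwise.
#'
#' @inheritParams king_robust
#' @return data.frame with columns `sample1`, `sample2` (canonical order),
#'   `phi`, `n_sites`.
#' @export
king_matrix <- function(geno, maf_min = 0.01, sites = NULL) {
  ds <- dosage(geno)
  af <- cohort_af(geno)
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf > maf_min
  if (!is.null(sites)) keep <- keep & seq_len(nrow(ds)) %in% sites
  ds <- ds[keep, , drop = FALSE]
  M <- !is.na(ds)
  dz <- ds; dz[!M] <- 3L # sentinel outside 0..2
  H <- (dz == 1L) * 1
  A0 <- (dz == 0L) * 1
  A2 <- (dz == 2L) * 1
  Mi <- M * 1
  n_aa <- crossprod(H)
  n_opp <- crossprod(A0, A2) + crossprod(A2, A0)
  het_vs <- crossprod(H, Mi) # het in row-sample among sites callable in col-sample
  denom <- het_vs + t(het_vs)
  phi <- (n_aa - 2 * n_opp) / denom
  n_sites <- crossprod(Mi)
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(sample1 = geno$samples[idx[, 1]], sample2 = geno$samples[idx[, 2]],
             phi = phi[idx], n_sites = as.integer(n_sites[idx]))
}

#' Merge IBD segments across short sparse gaps
#'
#' Within each (pair, haplotype-pair, chromosome) track, adjacent segments
#' are merged left-to-right until fixpoint when the gap between them is
#' shorter than `params$max_gap_cM` and contains at most
#' `params$max_discordant_homozygotes` opposite-homozygote sites for the
#' pair. Without genotypes only the gap-length rule applies (warned once).
#'
#' @param segments an `ibd_segments` data.frame.
#' @param geno optional `cohort_genotypes` for the discordance rule.
#' @param map a `genetic_map`.
#' @param params an `ibd_merge_params`.
#' @return merged `ibd_segments`.
#' @export
merge_ibd <- function(segments, geno = NULL, map, params = ibd_merge_params()) {
  segments <- validate_ibd(as.data.frame(segments))
  if (nrow(segments) == 0) return(segments)
  if (is.null(geno)) {
    warning("no genotypes supplied; merging on the gap rule only")
  }
  ds <- if (!is.null(geno)) dosage(geno) else NULL
  key <- paste(segments$sample1, segments$hap1, segments$sample2,
               segments$hap2, segments$chrom, sep = "\r")
  out <- lapply(split(segments, key), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    repeat {
      if (nrow(g) < 2) break
      merged_any <- FALSE
      i <- 1L
      while (i < nrow(g)) {
        gap_start <- g$end[i]
        gap_end <- g$start[i + 1]
        if (gap_start >= gap_end) { # touching or overlapping: always join
          ok <- TRUE
        } else {
          gap_cm <- cm_length(map, g$chrom[i], gap_start, gap_end)
          ok <- gap_cm < params$max_gap_cM
          if (ok && !is.null(ds)) {
            n_disc <- count_discordant(ds, geno, g$sample1[i], g$sample2[i],
                                       g$chrom[i], gap_start, gap_end)
            ok <- n_disc <= params$max_discordant_homozygotes
          }
        }
        if (ok) {
          g$end[i] <- max(g$end[i], g$end[i + 1])
          g$cM[i] <- cm_length(map, g$chrom[i], g$start[i], g$end[i])
          g <- g[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!merged_any) break
    }
    g
  })
  res <- do.call(rbind, out)
  validate_ibd(res)
}

# opposite-homozygote sites of a pair inside half-open [start, end)
count_discordant <- function(ds, geno, s1, s2, chrom, start, end) {
  sel <- geno$variants$chrom == chrom & geno$variants$pos - 1L >= start &
    geno$variants$pos - 1L < end
  if (!any(sel)) return(0L)
  gi <- ds[sel, s1]; gj <- ds[sel, s2]
  sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L), na.rm = TRUE)
}

#' Total IBD per pair
#'
#' Sum of segment cM lengths over all haplotype-pair channels and
#' chromosomes. Under this channel-sum convention a monozygotic pair totals
#' twice the map length and the kinship-equivalent divisor is `4 x L_tot`.
#'
#' @param segments an `ibd_segments`.
#' @return data.frame with columns `sample1`, `sample2`, `total_ibd_cM`.
#' @export
total_ibd <- function(segments) {
  if (nrow(segments) == 0) {
    return(data.frame(sample1 = character(), sample2 = character(),
                      total_ibd_cM = numeric()))
  }
  agg <- stats::aggregate(cM ~ sample1 + sample2, data = as.data.frame(segments), sum)
  names(agg)[3] <- "total_ibd_cM"
  agg[order(agg$sample1, agg$sample2), , drop = FALSE]
}

#' Classify relationship degree
#'
#' Either from a kinship coefficient directly, or from total IBD via the
#' kinship-equivalent `phi = total_ibd_cM / (4 * L_tot_cM)` under the
#' channel-sum convention.
#'
#' @param phi kinship coefficient(s); alternatively supply `total_ibd_cM`.
#' @param total_ibd_cM total IBD in cM (used with `L_tot_cM`).
#' @param L_tot_cM total map length in cM.
#' @param bins a `degree_bins`.
#' @return character vector of degree labels.
#' @export
classify_degree <- function(phi = NULL, total_ibd_cM = NULL, L_tot_cM = NULL,
                            bins = degree_bins()) {
  if (is.null(phi)) {
    if (is.null(total_ibd_cM) || is.null(L_tot_cM)) {
      stop_validation("supply phi, or total_ibd_cM with L_tot_cM")
    }
    phi <- total_ibd_cM / (4 * L_tot_cM)
  }
  out <- rep(bins$labels[length(bins$labels)], length(phi))
  for (k in rev(seq_along(bins$cuts))) {
    out[phi > bins$cuts[k]] <- bins$labels[k]
  }
  out[is.na(phi)] <- NA_character_
  out
}

#' Relatedness vs self-reported race concordance
#'
#' Joins pairwise total IBD (or kinship) with race labels and ancestry
#' categories; summarises how many related pairs (third degree or closer)
#' carry discordant race labels.
#'
#' @param pair_ibd data.frame with `sample1`, `sample2`, `total_ibd_cM`.
#' @param metadata a `sample_metadata`.
#' @param categories named sample->category vector.
#' @param L_tot_cM total map length in cM (for the degree call).
#' @param bins a `degree_bins`.
#' @return list with `pairs` (per-pair table: degree, races, categories,
#'   `same_race`) and `summary` (related-pair counts by race concordance;
#'   pairs with missing race are excluded and counted).
#' @export
race_concordance <- function(pair_ibd, metadata, categories, L_tot_cM,
                             bins = degree_bins()) {
  m <- as.data.frame(metadata)
  race <- setNames(m$race, m$sample)
  p <- as.data.frame(pair_ibd)
  p$race1 <- race[p$sample1]
  p$race2 <- race[p$sample2]
  miss <- is.na(p$race1) | is.na(p$race2)
  excluded <- sum(miss)
  p <- p[!miss, , drop = FALSE]
  p$degree <- classify_degree(total_ibd_cM = p$total_ibd_cM, L_tot_cM = L_tot_cM,
                              bins = bins)
  p$same_race <- p$race1 == p$race2
  p$category1 <- unname(categories[p$sample1])
  p$category2 <- unname(categories[p$sample2])
  related <- p$degree %in% setdiff(bins$labels, "unrelated")
  summary <- list(n_pairs = nrow(p),
                  n_excluded_missing_race = excluded,
                  n_related = sum(related),
                  n_related_same_race = sum(related & p$same_race),
                  n_related_discordant_race = sum(related & !p$same_race),
                  discordant_fraction = if (any(related)) {
                    sum(related & !p$same_race) / sum(related)
                  } else NA_real_)
  list(pairs = p, summary = summary)
}
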