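#' Classification thresholds for discrete ancestry categories
#'
#' Defaults mirror the published rules: an individual is single-ancestry when
#' one component exceeds 85% of the genome; two-way admixed when exactly the
#' two largest components each contribute at least 15% and jointly more than
#' 85%; multiway when three or more components each exceed 15%.
#'
#' @param single_min single-ancestry threshold (strict `>`, default 0.85).
#' @param pair_component_min per-component two-way threshold (`>=`, default 0.15).
#' @param pair_sum_min combined two-way threshold (strict `>`, default 0.85).
#' @param multi_component_min multiway per-component threshold (strict `>`,
#'   default 0.15).
#' @param named_pairs recognised two-way labels controlling display spelling
#'   (e.g. `"EUR-AFR"`); unrecognised pairs get a systematic alphabetical
#'   `X-Y` label.
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(single_min = 0.85, pair_component_min = 0.15,
                                      pair_sum_min = 0.85, multi_component_min = 0.15,
                                      named_pairs = c("EUR-AFR", "EUR-AMR")) {
  if (!(pair_component_min > 0 && pair_component_min < single_min && single_min <= 1)) {
    stop_validation("need 0 < pair_component_min < single_min <= 1")
  }
  structure(list(single_min = single_min, pair_component_min = pair_component_min,
                 pair_sum_min = pair_sum_min, multi_component_min = multi_component_min,
                 named_pairs = named_pairs),
            class = "classification_thresholds")
}

#' Geographic stratification parameters
#'
#' @param min_zone_n minimum individuals per zone for inclusion (default 100).
#' @param min_category_n minimum category size for dissimilarity (default 500).
#' @return object of class `geo_params`.
#' @export
geo_params <- function(min_zone_n = 100L, min_category_n = 500L) {
  if (min_zone_n < 1 || min_category_n < 1) stop_validation("geo thresholds must be positive")
  structure(list(min_zone_n = as.integer(min_zone_n),
                 min_category_n = as.integer(min_category_n)), class = "geo_params")
}

#' Global ancestry proportions from local-ancestry calls
#'
#' Per-sample, bp-weighted ancestry fractions over both haplotypes:
#' `proportion_k = bp covered by ancestry-k windows / (2 x total covered bp)`.
#'
#' @param calls a `local_ancestry`.
#' @param weight `"bp"` (default) or `"cM"` window weighting.
#' @return matrix (samples x ancestry labels) of proportions, rows sum to 1.
#' @export
global_from_tracts <- function(calls, weight = c("bp", "cM")) {
  stopifnot(inherits(calls, "local_ancestry"))
  weight <- match.arg(weight)
  w <- if (weight == "bp") {
    as.numeric(calls$windows$epos - calls$windows$spos)
  } else {
    calls$windows$egpos - calls$windows$sgpos
  }
  if (sum(w) <= 0) stop_validation("local ancestry windows cover zero length")
  labels <- names(sort(calls$codes))
  hap_tot <- matrix(0, nrow = length(labels), ncol = ncol(calls$calls),
                    dimnames = list(labels, colnames(calls$calls)))
  for (k in seq_along(labels)) {
    hap_tot[k, ] <- colSums(w * (calls$calls == calls$codes[[labels[k]]]))
  }
  n <- length(calls$samples)
  per_sample <- hap_tot[, 2 * seq_len(n) - 1, drop = FALSE] +
    hap_tot[, 2 * seq_len(n), drop = FALSE]
  prop <- t(per_sample) / (2 * sum(w))
  rownames(prop) <- calls$samples
  prop
}

#' Discrete ancestry categorisation
#'
#' Applies the threshold rules in order: (i) any component above `single_min`
#' gives that single label; (ii) otherwise, if the two largest components are
#' each at least `pair_component_min` and sum to more than `pair_sum_min`,
#' a two-way label; (iii) otherwise, three or more components above
#' `multi_component_min` give `MULTIWAY`; (iv) otherwise `UNASSIGNED`.
#'
#' @param proportions named proportion vector, or matrix (samples x labels)
#'   with ancestry labels as column names; each row must sum to 1.
#' @param thresholds a `classification_thresholds`.
#' @return character vector of category labels, one per row.
#' @export
classify_ancestry <- function(proportions, thresholds = classification_thresholds()) {
  if (is.null(dim(proportions))) {
    proportions <- matrix(proportions, nrow = 1,
                          dimnames = list(NULL, names(proportions)))
  }
  labels <- colnames(proportions)
  if (is.null(labels)) stop_validation("proportions need ancestry labels as names")
  if (any(abs(rowSums(proportions) - 1) > 1e-6) || any(proportions < -1e-12)) {
    stop_validation("each proportion vector must be non-negative and sum to 1")
  }
  th <- thresholds
  n <- nrow(proportions)
  i1 <- max.col(proportions, ties.method = "first")
  v1 <- proportions[cbind(seq_len(n), i1)]
  p2 <- proportions
  p2[cbind(seq_len(n), i1)] <- -Inf
  i2 <- max.col(p2, ties.method = "first")
  v2 <- proportions[cbind(seq_len(n), i2)]
  n_multi <- rowSums(proportions > th$multi_component_min)

  out <- rep("UNASSIGNED", n)
  multi <- n_multi >= 3L
  out[multi] <- "MULTIWAY"
  pair <- v1 >= th$pair_component_min & v2 >= th$pair_component_min &
    (v1 + v2) > th$pair_sum_min
  if (any(pair)) {
    la <- labels[i1[pair]]
    lb <- labels[i2[pair]]
    lab <- ifelse(la < lb, paste0(la, "-", lb), paste0(lb, "-", la))
    for (np in th$named_pairs) {
      parts <- sort(strsplit(np, "-", fixed = TRUE)[[1]])
      lab[lab == paste(parts, collapse = "-")] <- np
    }
    out[pair] <- lab
  }
  single <- v1 > th$single_min
  out[single] <- labels[i1[single]]
  setNames(out, rownames(proportions))
}

#' Drop an ancestry component and renormalise
#'
#' Removes one ancestry column from a proportion matrix (e.g. a negligible
#' reference group excluded from analysis) and, by default, rescales each
#' row to sum to 1 again so the categorisation rules stay applicable.
#'
#' @param proportions matrix from [global_from_tracts()].
#' @param label ancestry column to drop.
#' @param renormalize rescale rows to sum to 1 (default TRUE).
#' @return proportion matrix without `label`.
#' @export
drop_ancestry <- function(proportions, label, renormalize = TRUE) {
  if (!label %in% colnames(proportions)) {
    stop_validation("ancestry ", label, " not in proportion matrix")
  }
  out <- proportions[, setdiff(colnames(proportions), label), drop = FALSE]
  if (renormalize) {
    rs <- rowSums(out)
    if (any(rs <= 0)) stop_validation("a row has no remaining ancestry mass")
    out <- out / rs
  }
  out
}

#' Duncan dissimilarity index between two groups over zones
#'
#' `D = 0.5 * sum_z | a_z/A - b_z/B |`: 0 when the two groups are identically
#' distributed over zones, 1 under complete segregation. Zones whose total
#' head count falls below `geo$min_zone_n` are removed first.
#'
#' @param counts_a,counts_b named zone->count vectors for the two groups.
#' @param geo a `geo_params`.
#' @param zone_totals optional named cohort-wide zone totals used for the
#'   minimum-size filter; defaults to `counts_a + counts_b`.
#' @return dissimilarity index in `[0, 1]`.
#' @export
dissimilarity_index <- function(counts_a, counts_b, geo = geo_params(),
                                zone_totals = NULL) {
  na <- names(counts_a) %||% as.character(seq_along(counts_a))
  nb <- names(counts_b) %||% as.character(seq_along(counts_b))
  zones <- union(union(na, nb),
                 if (is.null(zone_totals)) character() else names(zone_totals))
  a <- setNames(rep(0, length(zones)), zones)
  b <- a
  a[na] <- counts_a
  b[nb] <- counts_b
  tot <- if (is.null(zone_totals)) a + b else {
    tt <- setNames(rep(0, length(zones)), zones)
    tt[names(zone_totals)] <- zone_totals
    tt
  }
  keep <- tot >= geo$min_zone_n
  a <- a[keep]; b <- b[keep]
  A <- sum(a); B <- sum(b)
  if (A <= 0 || B <= 0) {
    stop(errorCondition("dissimilarity undefined: a group has no individuals after zone filtering",
                        class = c("admixcohort_undefined", "error")))
  }
  0.5 * sum(abs(a / A - b / B))
}

#' Zone x ancestry-category composition table
#'
#' @param categories named character vector sample->category.
#' @param metadata a `sample_metadata`.
#' @param geo a `geo_params`; zones under `min_zone_n` are dropped and listed.
#' @return list with `counts` (zone x category matrix), `proportions`
#'   (rows sum to 1) and `dropped_zones`.
#' @export
zone_composition <- function(categories, metadata, geo = geo_params()) {
  m <- as.data.frame(metadata)
  if (!all(m$sample %in% names(categories))) {
    stop_validation("categories missing for some metadata samples")
  }
  cat_by_sample <- categories[m$sample]
  if (nrow(m) == 0) {
    return(list(counts = matrix(0L, 0, 0), proportions = matrix(0, 0, 0),
                dropped_zones = character()))
  }
  counts <- table(zone = m$zone, category = cat_by_sample)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  zn <- rowSums(counts)
  dropped <- rownames(counts)[zn < geo$min_zone_n]
  counts <- counts[zn >= geo$min_zone_n, , drop = FALSE]
  props <- counts / pmax(rowSums(counts), 1)
  list(counts = counts, proportions = props, dropped_zones = dropped)
}

#' Pairwise dissimilarity among large ancestry categories
#'
#' Computes the dissimilarity index for every pair of categories whose cohort
#' size reaches `geo$min_category_n`, using cohort-wide zone totals for the
#' zone filter.
#'
#' @inheritParams zone_composition
#' @return data.frame with columns `category_a`, `category_b`, `D`.
#' @export
dissimilarity_matrix <- function(categories, metadata, geo = geo_params()) {
  m <- as.data.frame(metadata)
  cat_by_sample <- categories[m$sample]
  zone_totals <- table(m$zone)
  sizes <- table(cat_by_sample)
  big <- names(sizes)[sizes >= geo$min_category_n]
  out <- list()
  if (length(big) >= 2) {
    for (i in seq_len(length(big) - 1)) {
      for (j in (i + 1):length(big)) {
        ca <- table(m$zone[cat_by_sample == big[i]])
        cb <- table(m$zone[cat_by_sample == big[j]])
        D <- dissimilarity_index(ca, cb, geo,
                                 zone_totals = setNames(as.integer(zone_totals),
                                                        names(zone_totals)))
        out[[length(out) + 1]] <- data.frame(category_a = big[i],
                                             category_b = big[j], D = D)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(category_a = character(), category_b = character(),
                      D = numeric()))
  }
  do.call(rbind, out)
}
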