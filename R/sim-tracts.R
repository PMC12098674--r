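# Dirichlet draw via normalised gammas
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(x)
  # degenerate all-zero rows (tiny alphas): fall back to a single category
  zero <- sw == 0
  if (any(zero)) {
    x[zero, ] <- 0
    x[cbind(which(zero), max.col(matrix(alpha, sum(zero), k, byrow = TRUE)))] <- 1
    sw[zero] <- 1
  }
  x / sw
}

#' Draw per-individual admixture proportions
#'
#' Samples each individual's proportion vector from the configured mixture of
#' Dirichlet subcohorts.
#'
#' @param config a `sim_config`.
#' @param n number of individuals.
#' @return matrix (n x K) with ancestry labels as column names.
#' @export
draw_admixture_proportions <- function(config, n) {
  comp <- sample.int(length(config$subcohorts), n, replace = TRUE,
                     prob = vapply(config$subcohorts, function(s) s$weight, 0))
  m <- matrix(0, n, config$K, dimnames = list(NULL, config$labels))
  for (k in seq_along(config$subcohorts)) {
    idx <- which(comp == k)
    if (length(idx)) {
      m[idx, ] <- rdirichlet(length(idx),
                             config$subcohorts[[k]]$alpha[config$labels])
    }
  }
  m
}

# Poisson-process breakpoints along one chromosome, returned as unique
# interior integer bp positions (0-based)
draw_breakpoints_bp <- function(chrom_row, rate_per_morgan) {
  l_morgan <- chrom_row$cM / 100
  k <- rpois(1, rate_per_morgan * l_morgan)
  if (k == 0) return(integer())
  bp <- round(sort(runif(k)) * chrom_row$bp)
  bp <- unique(bp[bp > 0 & bp < chrom_row$bp])
  as.integer(bp)
}

#' Simulate ancestry tracts for haplotypes (hybrid-isolation model)
#'
#' Breakpoints arrive as a Poisson process of rate `g` per Morgan; each
#' segment's ancestry is drawn i.i.d. from the proportion vector `m`;
#' adjacent segments with equal ancestry are merged, so the expected number
#' of visible switches per haplotype is `g * L * (1 - sum(m^2))` for a
#' chromosome of `L` Morgans.
#'
#' @param config a `sim_config`.
#' @param m proportion vector over the configured ancestries.
#' @param n_hap number of haplotypes to simulate (default 2, one diplotype).
#' @return data.frame with columns `hap`, `chrom`, `start`, `end` (0-based
#'   half-open bp) and `anc` (integer ancestry code, 0-based in label order);
#'   tracts tile each chromosome exactly.
#' @export
simulate_tracts <- function(config, m, n_hap = 2L) {
  if (length(m) != config$K || any(m < 0) || abs(sum(m) - 1) > 1e-8) {
    stop_validation("m must be a proportion vector over the configured ancestries")
  }
  out <- vector("list", n_hap * nrow(config$chrom))
  idx <- 0L
  for (h in seq_len(n_hap)) {
    for (ci in seq_len(nrow(config$chrom))) {
      cr <- config$chrom[ci, ]
      bp <- draw_breakpoints_bp(cr, config$g)
      bounds <- c(0L, bp, as.integer(cr$bp))
      n_seg <- length(bounds) - 1L
      anc <- sample.int(config$K, n_seg, replace = TRUE, prob = m) - 1L
      seg <- data.frame(hap = h, chrom = cr$chrom,
                        start = bounds[-length(bounds)], end = bounds[-1],
                        anc = anc)
      idx <- idx + 1L
      out[[idx]] <- merge_equal_adjacent(seg)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# collapse runs of identical ancestry in consecutive segments (one chromosome)
merge_equal_adjacent <- function(seg, col = "anc") {
  if (nrow(seg) <= 1) return(seg)
  r <- rle(seg[[col]])
  last <- cumsum(r$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  out <- seg[first, , drop = FALSE]
  out$end <- seg$end[last]
  out
}

# ancestry code at given 1-based positions for one haplotype's tracts
# (tracts must tile the chromosome)
tract_anc_at <- function(tracts, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    t0 <- tracts[tracts$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(t0) == 0) next
    i <- findInterval(pos[sel] - 1L, t0$start)
    ok <- i >= 1L & (pos[sel] - 1L) < t0$end[pmax(i, 1L)]
    out[sel[ok]] <- t0$anc[i[ok]]
  }
  out
}
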