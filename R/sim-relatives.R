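# --- haplotype mosaics -------------------------------------------------------
# A haplotype is a set of segments (chrom, start, end, src) tiling the genome,
# where src identifies the founder haplotype the segment descends from.
# Founder haplotypes are single-src tilings; gametes are mosaics produced by
# meiosis with Poisson crossovers at 1 per Morgan.

founder_hap_segments <- function(config, src_id) {
  data.frame(chrom = config$chrom$chrom, start = 0L,
             end = as.integer(config$chrom$bp), src = src_id)
}

# clip segments to half-open [s, e) on one chromosome
clip_segments <- function(segs, s, e) {
  keep <- segs$end > s & segs$start < e
  out <- segs[keep, , drop = FALSE]
  out$start <- pmax(out$start, s)
  out$end <- pmin(out$end, e)
  out
}

#' Meiosis: recombine two haplotypes into a gamete
#'
#' Crossovers arrive as a Poisson process at 1 per Morgan along each
#' chromosome; the gamete alternates between the two parental haplotypes,
#' starting from a random one, and carries their founder-source labels.
#'
#' @param hap_a,hap_b parental haplotype segment data.frames
#'   (`chrom`, `start`, `end`, `src`).
#' @param config a `sim_config` (chromosome lengths).
#' @return gamete segment data.frame in the same layout.
#' @export
meiosis <- function(hap_a, hap_b, config) {
  parents <- list(hap_a, hap_b)
  out <- list()
  for (ci in seq_len(nrow(config$chrom))) {
    cr <- config$chrom[ci, ]
    xo <- draw_breakpoints_bp(cr, 1)
    bounds <- c(0L, xo, as.integer(cr$bp))
    cur <- sample.int(2L, 1L)
    for (s in seq_len(length(bounds) - 1L)) {
      p <- parents[[cur]]
      seg <- clip_segments(p[p$chrom == cr$chrom, , drop = FALSE],
                           bounds[s], bounds[s + 1L])
      out[[length(out) + 1L]] <- seg
      cur <- 3L - cur
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, config$chrom$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  # merge contiguous pieces from the same source
  do.call(rbind, lapply(split(res, res$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    merge_equal_adjacent(g, col = "src")
  }))
}

# per-chromosome elementary decomposition of two genome tilings; returns the
# intervals where both haplotypes descend from the same founder haplotype
shared_src_intervals <- function(segs_i, segs_j) {
  out <- list()
  for (ch in unique(segs_i$chrom)) {
    a <- segs_i[segs_i$chrom == ch, , drop = FALSE]
    b <- segs_j[segs_j$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), ]; b <- b[order(b$start), ]
    cuts <- sort(unique(c(a$start, a$end, b$start, b$end)))
    s <- cuts[-length(cuts)]
    e <- cuts[-1]
    src_a <- a$src[findInterval(s, a$start)]
    src_b <- b$src[findInterval(s, b$start)]
    same <- !is.na(src_a) & !is.na(src_b) & src_a == src_b
    if (!any(same)) next
    d <- data.frame(chrom = ch, start = s[same], end = e[same], anc = 1L)
    # merge touching runs
    run <- cumsum(c(1L, as.integer(d$start[-1] != d$end[-nrow(d)])))
    r <- rle(run)
    last <- cumsum(r$lengths); first <- c(1L, head(last, -1L) + 1L)
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = d$start[first],
                                          end = d$end[last])
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  do.call(rbind, out)
}

#' True IBD segments between two simulated individuals
#'
#' Intersects the founder-source mosaics of all four haplotype channels; a
#' region is IBD when both haplotypes descend from the same founder
#' haplotype.
#'
#' @param ind_i,ind_j individuals as `list(hap1 = segments, hap2 = segments)`.
#' @param id_i,id_j sample identifiers for the output rows.
#' @param config a `sim_config` (for cM conversion).
#' @return an `ibd_segments` data.frame (possibly empty).
#' @export
true_ibd_segments <- function(ind_i, ind_j, id_i, id_j, config) {
  cm_per_bp <- setNames(config$chrom$cM / config$chrom$bp, config$chrom$chrom)
  rows <- list()
  for (h1 in 1:2) {
    for (h2 in 1:2) {
      shared <- shared_src_intervals(ind_i[[h1]], ind_j[[h2]])
      if (nrow(shared) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample1 = id_i, hap1 = h1, sample2 = id_j, hap2 = h2,
        chrom = shared$chrom, start = shared$start, end = shared$end,
        cM = (shared$end - shared$start) * cm_per_bp[shared$chrom])
    }
  }
  if (!length(rows)) {
    return(validate_ibd(data.frame(sample1 = character(), hap1 = integer(),
                                   sample2 = character(), hap2 = integer(),
                                   chrom = character(), start = integer(),
                                   end = integer(), cM = numeric())))
  }
  validate_ibd(do.call(rbind, rows))
}

#' Simulate a pedigree over admixed founders
#'
#' Founders (rows with both parents `NA`) receive fresh ancestry tracts drawn
#' from the configured admixture model; non-founders are produced by meiosis
#' of their parents' haplotypes. The pedigree must be acyclic.
#'
#' @param config a `sim_config`.
#' @param pedigree data.frame with columns `id`, `father`, `mother` (`NA`
#'   for founders).
#' @param m optional matrix of founder admixture proportions (rows named by
#'   founder id); drawn from the config when absent.
#' @return list with `individuals` (named list of `list(hap1, hap2)` source
#'   mosaics), `founder_tracts` (ancestry tracts keyed by founder haplotype
#'   id), `hap_ids` (2-column matrix of haplotype ids per individual) and
#'   `founder_m` (the founder proportions used).
#' @export
simulate_relatives <- function(config, pedigree, m = NULL) {
  ped <- as.data.frame(pedigree)
  if (anyDuplicated(ped$id)) stop_validation("duplicate pedigree id")
  is_founder <- is.na(ped$father) & is.na(ped$mother)
  if (any(is.na(ped$father) != is.na(ped$mother))) {
    stop_validation("individuals need both parents or neither")
  }
  # topological order by repeated peeling; failure to peel => cycle
  done <- character()
  order_ids <- character()
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- is.na(remaining$father) |
      (remaining$father %in% done & remaining$mother %in% done)
    if (!any(ready)) stop_validation("pedigree contains a cycle or missing parent")
    order_ids <- c(order_ids, remaining$id[ready])
    done <- c(done, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  founders <- ped$id[is_founder]
  if (is.null(m)) {
    m <- draw_admixture_proportions(config, length(founders))
    rownames(m) <- founders
  }
  individuals <- list()
  founder_tracts <- list()
  hap_ids <- matrix(NA_integer_, nrow(ped), 2, dimnames = list(ped$id, NULL))
  next_hap <- 1L
  for (id in order_ids) {
    row <- ped[ped$id == id, ]
    if (is.na(row$father)) {
      haps <- list()
      for (h in 1:2) {
        tr <- simulate_tracts(config, m[id, ], n_hap = 1L)
        founder_tracts[[as.character(next_hap)]] <-
          tr[, c("chrom", "start", "end", "anc")]
        haps[[h]] <- founder_hap_segments(config, next_hap)
        hap_ids[id, h] <- next_hap
        next_hap <- next_hap + 1L
      }
      individuals[[id]] <- list(hap1 = haps[[1]], hap2 = haps[[2]])
    } else {
      fa <- individuals[[row$father]]
      mo <- individuals[[row$mother]]
      individuals[[id]] <- list(hap1 = meiosis(fa$hap1, fa$hap2, config),
                                hap2 = meiosis(mo$hap1, mo$hap2, config))
    }
  }
  list(individuals = individuals, founder_tracts = founder_tracts,
       hap_ids = hap_ids, founder_m = m)
}

# ancestry tracts of an arbitrary (possibly mosaic) haplotype: intersect its
# source segments with the founder tracts they descend from
compose_tracts <- function(hap_segs, founder_tracts) {
  out <- list()
  for (r in seq_len(nrow(hap_segs))) {
    ft <- founder_tracts[[as.character(hap_segs$src[r])]]
    piece <- clip_segments(ft[ft$chrom == hap_segs$chrom[r], , drop = FALSE],
                           hap_segs$start[r], hap_segs$end[r])
    out[[length(out) + 1L]] <- piece[, c("chrom", "start", "end", "anc")]
  }
  res <- do.call(rbind, out)
  do.call(rbind, lapply(split(res, res$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    merge_equal_adjacent(g, col = "anc")
  }))
}
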