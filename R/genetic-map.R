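#' Genetic map: bp to cM interpolation
#'
#' A genetic map holds, per chromosome, a set of anchor points `(pos bp, cM)`
#' that must be non-decreasing in both coordinates. Positions between anchors
#' are interpolated linearly; positions beyond the terminal anchors are
#' extrapolated with the slope of the nearest interval.
#'
#' @param anchors data.frame with columns `chrom`, `pos` (bp, 1-based) and
#'   `cM`.
#' @return object of class `genetic_map`.
#' @export
genetic_map <- function(anchors) {
  anchors <- as.data.frame(anchors)
  need <- c("chrom", "pos", "cM")
  if (!all(need %in% names(anchors))) {
    stop_format("genetic map needs columns: ", paste(need, collapse = ", "))
  }
  anchors$chrom <- normalize_chrom(anchors$chrom)
  anchors <- anchors[order(anchors$chrom, anchors$pos), ]
  by_chrom <- split(anchors[c("pos", "cM")], anchors$chrom)
  for (ch in names(by_chrom)) {
    a <- by_chrom[[ch]]
    if (nrow(a) < 2) {
      stop_validation("genetic map: chromosome ", ch, " has fewer than 2 anchors")
    }
    if (is.unsorted(a$pos, strictly = TRUE)) {
      stop_validation("genetic map: duplicated or non-increasing bp anchors on ", ch)
    }
    if (is.unsorted(a$cM)) {
      stop_validation("genetic map: non-monotone cM anchors on ", ch)
    }
  }
  structure(list(anchors = by_chrom, constant_rate = NULL), class = "genetic_map")
}

#' Constant-rate genetic map
#'
#' Fallback map at a uniform rate (default 1 cM/Mb) used when no empirical
#' map is available; construction emits a warning so the approximation is
#' visible in logs.
#'
#' @param rate_cm_per_mb recombination rate in cM per megabase.
#' @param warn warn about the approximation (default TRUE).
#' @return object of class `genetic_map`.
#' @export
constant_map <- function(rate_cm_per_mb = 1, warn = TRUE) {
  if (warn) warning("no genetic map supplied; using constant ", rate_cm_per_mb, " cM/Mb")
  structure(list(anchors = NULL, constant_rate = rate_cm_per_mb), class = "genetic_map")
}

#' Interpolate genetic positions
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos positions in bp.
#' @return genetic positions in cM.
#' @export
cm_at <- function(map, chrom, pos) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(map$constant_rate)) {
    return(pos / 1e6 * map$constant_rate)
  }
  chrom <- normalize_chrom(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    a <- map$anchors[[ch]]
    if (is.null(a)) stop_validation("genetic map has no anchors for ", ch)
    i <- chrom == ch
    out[i] <- linear_extrap(a$pos, a$cM, pos[i])
  }
  out
}

# linear interpolation with straight-line extrapolation past terminal anchors
linear_extrap <- function(x, y, xout) {
  res <- approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    res[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    res[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  res
}

#' Genetic length of intervals
#'
#' cM length of half-open bp intervals `[start, end)`.
#'
#' @param map a `genetic_map`.
#' @param chrom,start,end parallel vectors describing the intervals.
#' @return lengths in cM.
#' @export
cm_length <- function(map, chrom, start, end) {
  if (any(start >= end)) stop_validation("interval with start >= end")
  cm_at(map, chrom, end) - cm_at(map, chrom, start)
}
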