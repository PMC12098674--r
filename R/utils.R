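#' @import data.table
#' @importFrom stats rbinom rbeta rpois runif setNames approx qnorm quantile
#' @importFrom utils head tail
NULL

# validation failures are thrown with a dedicated condition class so tests can
# distinguish bad input from programming errors
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("admixcohort_validation", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("admixcohort_format", "error")))
}

#' Normalise chromosome names
#'
#' Accepts `1` and `chr1` style names; everything is stored as `chr1`.
#'
#' @param x character vector of chromosome names.
#' @return character vector with a `chr` prefix.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# deterministic per-stage RNG substream: hash the stage name into an offset so
# stages can be re-run independently under one pipeline seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# canonical unordered pair ids: smaller sample id first (string order)
canonical_pair <- function(s1, s2) {
  swap <- s1 > s2
  list(a = ifelse(swap, s2, s1), b = ifelse(swap, s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
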