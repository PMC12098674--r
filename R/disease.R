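#' 2x2 contingency table
#'
#' @param a exposed cases.
#' @param b exposed controls.
#' @param c unexposed cases.
#' @param d unexposed controls.
#' @return object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) stop_validation("cell counts must be non-negative integers")
  if (sum(v) <= 0) stop_validation("empty 2x2 table")
  structure(as.list(v), class = "table2x2")
}

#' Wald confidence interval for a prevalence
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, truncated to `[0, 1]`.
#'
#' @param cases number of cases.
#' @param n group size (> 0).
#' @param conf confidence level (default 0.95).
#' @return list with `cases`, `n`, `p_hat`, `ci_low`, `ci_high`.
#' @export
prevalence_ci <- function(cases, n, conf = 0.95) {
  if (any(n <= 0)) stop_validation("prevalence needs n > 0")
  if (any(cases < 0 | cases > n)) stop_validation("cases must lie in [0, n]")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- cases / n
  half <- z * sqrt(p * (1 - p) / n)
  list(cases = cases, n = n, p_hat = p,
       ci_low = pmax(0, p - half), ci_high = pmin(1, p + half))
}

#' Odds ratio with Woolf (log-OR) confidence interval
#'
#' `OR = ad/(bc)`; `se(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell
#' is zero, the Haldane-Anscombe correction adds 0.5 to all four cells and
#' the result is flagged `corrected`.
#'
#' @param tab a `table2x2` (or list with elements a, b, c, d).
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `log_or`, `log_se`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @export
odds_ratio <- function(tab, conf = 0.95) {
  v <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- any(v == 0)
  if (corrected) v <- v + 0.5
  z <- qnorm(1 - (1 - conf) / 2)
  log_or <- log(v[1]) + log(v[4]) - log(v[2]) - log(v[3])
  se <- sqrt(sum(1 / v))
  list(or = exp(log_or), log_or = log_or, log_se = se,
       ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
       corrected = corrected)
}

#' Mantel-Haenszel pooled odds ratio
#'
#' Pooled estimate `OR_MH = sum(a_k d_k / n_k) / sum(b_k c_k / n_k)` with the
#' Robins-Breslow-Greenland variance for `log(OR_MH)`. Strata with an empty
#' margin (no cases, no controls, no exposed or no unexposed) are dropped and
#' counted.
#'
#' @param tables list of `table2x2`.
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `log_or`, `log_se`, `ci_low`, `ci_high`,
#'   `k` (strata used), `dropped` (strata removed), `strata` (per-stratum
#'   [odds_ratio()] results for the retained strata).
#' @export
mantel_haenszel <- function(tables, conf = 0.95) {
  if (length(tables) < 1) stop_validation("Mantel-Haenszel needs at least one stratum")
  m <- do.call(rbind, lapply(tables, function(t) c(t$a, t$b, t$c, t$d)))
  a <- m[, 1]; b <- m[, 2]; cc <- m[, 3]; d <- m[, 4]
  ok <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  dropped <- sum(!ok)
  a <- a[ok]; b <- b[ok]; cc <- cc[ok]; d <- d[ok]
  n <- a + b + cc + d
  R <- a * d / n
  S <- b * cc / n
  if (length(n) == 0 || sum(S) == 0 || sum(R) == 0) {
    return(list(or = NA_real_, log_or = NA_real_, log_se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, k = length(n),
                dropped = dropped, defined = FALSE, strata = list()))
  }
  P <- (a + d) / n
  Q <- (b + cc) / n
  or_mh <- sum(R) / sum(S)
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(var_log)
  z <- qnorm(1 - (1 - conf) / 2)
  strata <- lapply(which(ok), function(i) odds_ratio(tables[[i]], conf))
  list(or = or_mh, log_or = log(or_mh), log_se = se,
       ci_low = exp(log(or_mh) - z * se), ci_high = exp(log(or_mh) + z * se),
       k = length(n), dropped = dropped, defined = TRUE, strata = strata)
}

# build a condition's 2x2 table against a binary exposure; NA phenotype
# states are excluded from both margins
condition_table <- function(metadata, condition, exposed) {
  v <- metadata[[condition]]
  if (is.null(v)) stop_validation("condition ", condition, " not in metadata")
  use <- !is.na(v)
  case <- v[use] == "case"
  e <- exposed[use]
  table2x2(sum(case & e), sum(!case & e), sum(case & !e), sum(!case & !e))
}

#' Target-condition odds ratios against a random-condition reference panel
#'
#' Computes per-condition odds ratios for the target conditions under a binary
#' exposure (by default self-reported non-White vs White), then samples
#' `n_ref` non-target conditions without replacement and pools their tables
#' with the Mantel-Haenszel method as the reference. Mirrors the published
#' comparison of four health-disparity conditions against 200 random
#' conditions.
#'
#' @param metadata a `sample_metadata`.
#' @param targets character vector of target condition column names.
#' @param n_ref number of reference conditions to sample (default 200).
#' @param exposure logical vector (per metadata row) giving the exposed group,
#'   or NULL to use `race != white_label`.
#' @param white_label race label treated as unexposed (default `"White"`).
#' @param min_cases minimum total case count for a condition to enter the
#'   reference candidate pool (default 20).
#' @param seed RNG seed for the reference sample.
#' @return list with `targets` (data.frame of per-target OR results),
#'   `reference` (the pooled [mantel_haenszel()] result), and
#'   `reference_conditions`.
#' @export
reference_panel_or <- function(metadata, targets, n_ref = 200L, exposure = NULL,
                               white_label = "White", min_cases = 20L,
                               seed = 1L) {
  conds <- attr(metadata, "conditions")
  if (is.null(conds)) conds <- setdiff(names(metadata), c("sample", "race", "zone", "age"))
  missing_t <- setdiff(targets, conds)
  if (length(missing_t)) stop_validation("target conditions not in metadata: ",
                                         paste(missing_t, collapse = ", "))
  if (is.null(exposure)) exposure <- metadata$race != white_label
  if (sum(exposure, na.rm = TRUE) == 0 || sum(!exposure, na.rm = TRUE) == 0) {
    stop_validation("both exposure groups must be non-empty")
  }
  candidates <- setdiff(conds, targets)
  n_case <- vapply(candidates, function(cn) sum(metadata[[cn]] == "case", na.rm = TRUE), 0)
  candidates <- candidates[n_case >= min_cases]
  if (length(candidates) < n_ref) {
    stop_validation("only ", length(candidates), " candidate reference conditions; need ", n_ref)
  }
  set.seed(seed)
  ref_conds <- sort(sample(candidates, n_ref))
  ref_tabs <- lapply(ref_conds, function(cn) condition_table(metadata, cn, exposure))
  pooled <- mantel_haenszel(ref_tabs)
  tgt <- do.call(rbind, lapply(targets, function(cn) {
    o <- odds_ratio(condition_table(metadata, cn, exposure))
    data.frame(condition = cn, or = o$or, ci_low = o$ci_low, ci_high = o$ci_high,
               corrected = o$corrected,
               above_reference = o$ci_low > pooled$ci_high)
  }))
  list(targets = tgt, reference = pooled, reference_conditions = ref_conds)
}

#' Case counts by ancestry category and age group
#'
#' @param metadata a `sample_metadata`.
#' @param categories named sample->category vector.
#' @param conditions condition column names (default: all).
#' @param age_split age in years separating children from adults (default 18;
#'   missing ages fall in an `unknown` stratum).
#' @return data.frame with columns `condition`, `age_group`, `category`,
#'   `cases`.
#' @export
case_counts_by_group <- function(metadata, categories, conditions = NULL,
                                 age_split = 18) {
  conds <- conditions %||% attr(metadata, "conditions")
  cat_by_sample <- categories[metadata$sample]
  age_group <- ifelse(is.na(metadata$age), "unknown",
                      ifelse(metadata$age < age_split, "child", "adult"))
  out <- list()
  for (cn in conds) {
    case <- !is.na(metadata[[cn]]) & metadata[[cn]] == "case"
    if (!any(case)) {
      out[[cn]] <- data.frame(condition = cn, age_group = NA_character_,
                              category = NA_character_, cases = 0L)
      next
    }
    tb <- as.data.frame(table(age_group = age_group[case],
                              category = cat_by_sample[case]),
                        stringsAsFactors = FALSE)
    tb <- tb[tb$Freq > 0, , drop = FALSE]
    out[[cn]] <- data.frame(condition = cn, age_group = tb$age_group,
                            category = tb$category, cases = tb$Freq)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
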