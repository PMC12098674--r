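#' Synthetic admixed-cohort configuration
#'
#' Defines the generative model for a K-ancestry admixed cohort with tract
#' structure: admixture happened once, `g` generations ago, so tract
#' boundaries accumulate as a Poisson process of rate `g` per Morgan and
#' tract ancestries are drawn i.i.d. from each individual's admixture
#' proportions (hybrid-isolation model). Allele frequencies are
#' ancestry-specific; catalog membership (the `known` flag), self-reported
#' race, residential zone and disease risk all depend on ancestry so that
#' every downstream statistic has a recoverable generative expectation.
#'
#' @param labels ancestry labels (codes are assigned 0..K-1 in this order).
#' @param g generations since admixture (tract switch rate per Morgan).
#' @param subcohorts mixture of Dirichlet components for per-individual
#'   admixture proportions: list of `list(weight, alpha)` with `alpha` named
#'   by ancestry.
#' @param chrom data.frame with `chrom`, `bp`, `cM` (one row per chromosome).
#' @param n_variants total variant count across the genome.
#' @param n_samples number of unrelated cohort individuals (relatives are
#'   added on top).
#' @param freq_model list with Beta parameters `functional` and `modifier`
#'   (per-ancestry frequencies for HIGH/MODERATE/LOW vs MODIFIER variants)
#'   and optional `deleterious_ratio = list(num, den, ratio)` forcing
#'   deleterious-variant frequencies in ancestry `num` to be `ratio` times
#'   those in `den`.
#' @param annotation_model list with `impact_probs` (named over
#'   HIGH/MODERATE/LOW/MODIFIER) and Beta parameters `sift`, `polyphen` for
#'   missense scores.
#' @param catalog_model named per-ancestry probability that a variant whose
#'   origin (argmax frequency) is that ancestry is present in reference
#'   catalogs.
#' @param race_labels self-reported race vocabulary.
#' @param race_discordance probability `d` that an individual reports a race
#'   other than the one implied by their ancestry category (spread uniformly
#'   over the other labels).
#' @param zone_model list with `n_zones` and Dirichlet `alpha` for zone
#'   ancestry mixtures, or a fixed `weights` matrix (zones x ancestries).
#' @param disease_model list with `targets` (named list of
#'   `list(intercept, category_effects, zone_sd)`), `n_null` null conditions
#'   and `null_logit_range` for their intercepts.
#' @param relatives named counts of related pairs to add:
#'   `po` (parent-offspring), `fs` (full siblings), `hs` (half siblings),
#'   `c1` (first cousins), `mz` (monozygotic duplicates).
#' @param prop_children fraction of the cohort under 18 years (default 0.87).
#' @param seed integer seed; the same seed reproduces the cohort
#'   byte-for-byte.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(labels = c("AFR", "AMR", "EAS", "EUR"),
                       g = 12,
                       subcohorts = default_subcohorts(labels),
                       chrom = data.frame(chrom = c("chr1", "chr2"),
                                          bp = 1e7, cM = 100),
                       n_variants = 5000L,
                       n_samples = 200L,
                       freq_model = list(functional = c(0.35, 120),
                                         modifier = c(0.8, 8),
                                         deleterious_ratio = NULL),
                       annotation_model = list(
                         impact_probs = c(HIGH = 0.03, MODERATE = 0.17,
                                          LOW = 0.20, MODIFIER = 0.60),
                         sift = c(0.5, 1.5), polyphen = c(1.5, 0.5)),
                       catalog_model = c(AFR = 0.88, AMR = 0.80,
                                         EAS = 0.90, EUR = 0.99),
                       race_labels = c("Black", "Hispanic", "Asian", "White",
                                       "Other"),
                       race_discordance = 0.1,
                       zone_model = list(n_zones = 12L, alpha = 0.3),
                       disease_model = default_disease_model(),
                       relatives = c(po = 3L, fs = 4L, hs = 4L, c1 = 4L,
                                     mz = 1L),
                       prop_children = 0.87,
                       seed = 1L) {
  if (g <= 0) stop_validation("g must be positive")
  if (length(labels) < 2) stop_validation("need at least two ancestries")
  chrom <- as.data.frame(chrom)
  chrom$chrom <- normalize_chrom(chrom$chrom)
  if (any(chrom$bp <= 0 | chrom$cM <= 0)) stop_validation("chromosome lengths must be positive")
  wts <- vapply(subcohorts, function(s) s$weight, 0)
  if (abs(sum(wts) - 1) > 1e-8) stop_validation("subcohort weights must sum to 1")
  for (s in subcohorts) {
    if (!setequal(names(s$alpha), labels)) {
      stop_validation("subcohort alpha must be named by the ancestry labels")
    }
  }
  if (!all(labels %in% names(catalog_model))) {
    stop_validation("catalog_model must name every ancestry")
  }
  if (any(catalog_model < 0 | catalog_model > 1) ||
      race_discordance < 0 || race_discordance > 1) {
    stop_validation("probabilities must lie in [0,1]")
  }
  p <- annotation_model$impact_probs
  if (!setequal(names(p), IMPACT_LEVELS) || abs(sum(p) - 1) > 1e-8) {
    stop_validation("impact_probs must cover HIGH/MODERATE/LOW/MODIFIER and sum to 1")
  }
  structure(list(labels = labels, K = length(labels), g = g,
                 subcohorts = subcohorts, chrom = chrom,
                 n_variants = as.integer(n_variants),
                 n_samples = as.integer(n_samples),
                 freq_model = freq_model, annotation_model = annotation_model,
                 catalog_model = catalog_model[labels],
                 race_labels = race_labels,
                 race_discordance = race_discordance,
                 zone_model = zone_model, disease_model = disease_model,
                 relatives = relatives, prop_children = prop_children,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_subcohorts <- function(labels = c("AFR", "AMR", "EAS", "EUR")) {
  al <- function(...) {
    a <- c(...)
    setNames(a[labels], labels)
  }
  list(
    list(weight = 0.30, alpha = al(AFR = 40, AMR = 0.5, EAS = 0.5, EUR = 2)),
    list(weight = 0.28, alpha = al(AFR = 2, AMR = 0.5, EAS = 0.5, EUR = 40)),
    list(weight = 0.22, alpha = al(AFR = 12, AMR = 0.5, EAS = 0.5, EUR = 8)),
    list(weight = 0.10, alpha = al(AFR = 0.5, AMR = 10, EAS = 0.5, EUR = 10)),
    list(weight = 0.04, alpha = al(AFR = 0.5, AMR = 0.5, EAS = 30, EUR = 2)),
    list(weight = 0.06, alpha = al(AFR = 5, AMR = 5, EAS = 5, EUR = 5)))
}

#' @rdname sim_config
#' @export
default_disease_model <- function() {
  minority <- c(AFR = 1, "EUR-AFR" = 1, AMR = 1, "EUR-AMR" = 1)
  list(
    targets = list(
      asthma = list(intercept = stats::qlogis(0.12),
                    category_effects = 1.0 * minority, zone_sd = 0.2),
      obesity = list(intercept = stats::qlogis(0.15),
                     category_effects = 0.9 * minority, zone_sd = 0.2),
      diabetes = list(intercept = stats::qlogis(0.05),
                      category_effects = 0.4 * minority, zone_sd = 0.1),
      hypertension = list(intercept = stats::qlogis(0.08),
                          category_effects = 0.4 * minority, zone_sd = 0.1)),
    n_null = 240L,
    null_logit_range = c(-3.2, -2.2))
}
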