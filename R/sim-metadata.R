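# race label implied by an ancestry category (deterministic base mapping);
# discordance then moves mass off this diagonal
base_race_for_category <- function(category, race_labels) {
  out <- rep("Other", length(category))
  out[grepl("EAS", category)] <- "Asian"
  out[grepl("AMR", category)] <- "Hispanic"
  out[grepl("AFR", category)] <- "Black"
  out[category == "EUR"] <- "White"
  out[!out %in% race_labels] <- race_labels[length(race_labels)]
  out
}

#' Race-confusion matrix implied by a configuration
#'
#' Rows are ancestry categories, columns self-reported race labels: mass
#' `1 - d` on the category's base race and `d` spread uniformly over the
#' other labels. Rows sum to 1.
#'
#' @param categories category labels to build rows for.
#' @param config a `sim_config`.
#' @return row-stochastic matrix (categories x race labels).
#' @export
race_confusion_matrix <- function(categories, config) {
  categories <- unique(categories)
  rl <- config$race_labels
  d <- config$race_discordance
  m <- matrix(d / (length(rl) - 1), length(categories), length(rl),
              dimnames = list(categories, rl))
  base <- base_race_for_category(categories, rl)
  m[cbind(seq_along(categories), match(base, rl))] <- 1 - d
  if (any(abs(rowSums(m) - 1) > 1e-9)) stop_validation("confusion rows must sum to 1")
  m
}

#' Simulate sample metadata (race, zone, age, phenotypes)
#'
#' Race is drawn from the confusion row of the individual's ancestry
#' category; the residential zone is drawn proportionally to the zone
#' mixture weight of the individual's dominant ancestry; disease status is
#' Bernoulli in a logistic model with an intercept, per-category effects and
#' per-zone effects. Null reference conditions carry an intercept only.
#'
#' @param config a `sim_config`.
#' @param samples sample identifiers.
#' @param categories ancestry category per sample.
#' @param dominant dominant-ancestry label per sample.
#' @return list with `metadata` (a `sample_metadata`) and `params` (the
#'   realised zone weights, confusion matrix and condition parameters).
#' @export
simulate_metadata <- function(config, samples, categories, dominant) {
  n <- length(samples)
  zm <- config$zone_model
  if (!is.null(zm$weights)) {
    W <- zm$weights
    if (any(W < 0)) stop_validation("zone weights must be non-negative")
  } else {
    W <- rdirichlet(zm$n_zones, rep(zm$alpha, config$K))
    colnames(W) <- config$labels
  }
  zones <- paste0("Z", formatC(seq_len(nrow(W)), width = 2, flag = "0"))
  rownames(W) <- zones

  conf <- race_confusion_matrix(unique(categories), config)
  race <- character(n)
  for (cat in rownames(conf)) {
    idx <- which(categories == cat)
    race[idx] <- sample(colnames(conf), length(idx), replace = TRUE,
                        prob = conf[cat, ])
  }

  zone <- character(n)
  for (k in config$labels) {
    idx <- which(dominant == k)
    if (length(idx)) {
      zone[idx] <- sample(zones, length(idx), replace = TRUE, prob = W[, k])
    }
  }

  child <- runif(n) < config$prop_children
  age <- ifelse(child, sample(0:17, n, replace = TRUE),
                sample(18:89, n, replace = TRUE))

  dm <- config$disease_model
  missing_rate <- dm$missing_rate %||% 0.02
  meta <- data.frame(sample = samples, race = race, zone = zone, age = age,
                     stringsAsFactors = FALSE)
  cond_params <- list()
  draw_condition <- function(intercept, cat_eff, zone_eff) {
    eff <- rep(0, n)
    hit <- categories %in% names(cat_eff)
    if (any(hit)) eff[hit] <- cat_eff[categories[hit]]
    eta <- intercept + eff + zone_eff[zone]
    status <- ifelse(runif(n) < stats::plogis(eta), "case", "control")
    status[runif(n) < missing_rate] <- NA
    status
  }
  for (cn in names(dm$targets)) {
    t <- dm$targets[[cn]]
    zone_eff <- setNames(stats::rnorm(length(zones), 0, t$zone_sd %||% 0), zones)
    meta[[cn]] <- draw_condition(t$intercept, t$category_effects, zone_eff)
    cond_params[[cn]] <- list(intercept = t$intercept,
                              category_effects = t$category_effects,
                              zone_effects = zone_eff)
  }
  if ((dm$n_null %||% 0) > 0) {
    null_int <- runif(dm$n_null, dm$null_logit_range[1], dm$null_logit_range[2])
    zero_eff <- setNames(rep(0, length(zones)), zones)
    for (j in seq_len(dm$n_null)) {
      cn <- paste0("COND_", formatC(j, width = 3, flag = "0"))
      meta[[cn]] <- draw_condition(null_int[j], c(), zero_eff)
      cond_params[[cn]] <- list(intercept = null_int[j])
    }
  }
  list(metadata = validate_metadata(meta),
       params = list(zone_weights = W, confusion = conf,
                     conditions = cond_params))
}
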