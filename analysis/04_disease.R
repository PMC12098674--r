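#!/usr/bin/env Rscript
# Disease stratification: case counts by ancestry category (children vs
# adults), zone prevalence with Wald intervals, and target-condition odds
# ratios (non-White vs White self-report) against a Mantel-Haenszel pooled
# reference of 200 randomly sampled conditions.

suppressPackageStartupMessages(library(admixcohort))

seed <- 1L
meta <- read_metadata("results/cohort/metadata.tsv")
calls <- read_msp("results/cohort/local_ancestry.msp.tsv")
cats <- classify_ancestry(global_from_tracts(calls))

targets <- c("asthma", "obesity", "diabetes", "hypertension")

cc <- case_counts_by_group(meta, cats, targets)
data.table::fwrite(cc, "results/case_counts.tsv", sep = "\t")
cat("cases by condition and age group:\n")
print(stats::xtabs(cases ~ condition + age_group, cc))

# zone prevalence for the two headline conditions
zones <- names(which(table(meta$zone) >= 20))
prev <- do.call(rbind, lapply(c("asthma", "obesity"), function(cn) {
  do.call(rbind, lapply(zones, function(z) {
    v <- meta[[cn]][meta$zone == z]
    v <- v[!is.na(v)]
    p <- prevalence_ci(sum(v == "case"), length(v))
    data.frame(condition = cn, zone = z, cases = p$cases, n = p$n,
               prevalence = p$p_hat, ci_low = p$ci_low, ci_high = p$ci_high)
  }))
}))
data.table::fwrite(prev, "results/zone_prevalence.tsv", sep = "\t")

rp <- reference_panel_or(meta, targets, n_ref = 200, min_cases = 5, seed = seed)
data.table::fwrite(rp$targets, "results/disease_target_or.tsv", sep = "\t")
cat(sprintf("\npooled reference OR over %d random conditions: %.3f [%.3f, %.3f]\n",
            rp$reference$k, rp$reference$or, rp$reference$ci_low,
            rp$reference$ci_high))
cat("\ntarget odds ratios (non-White vs White):\n")
print(rp$targets, row.names = FALSE)
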