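#!/usr/bin/env Rscript
# Relatedness: KING-robust kinship over all pairs, IBD-segment
# post-processing (gap/discordant-homozygote merging), total IBD, degree
# classification, and concordance of relatedness with self-reported race.

suppressPackageStartupMessages(library(admixcohort))

geno <- read_phased_vcf("results/cohort/cohort.vcf")
calls <- read_msp("results/cohort/local_ancestry.msp.tsv")
map <- read_genetic_map("results/cohort/genetic_map.tsv")
meta <- read_metadata("results/cohort/metadata.tsv")
ibd <- read_ibd("results/cohort/ibd_truth.tsv")
cats <- classify_ancestry(global_from_tracts(calls))

kin <- king_matrix(geno)
kin$degree <- classify_degree(phi = kin$phi)
data.table::fwrite(kin, "results/kinship.tsv", sep = "\t")
cat("pairs by inferred degree (KING-robust):\n")
print(table(kin$degree))

merged <- merge_ibd(ibd, geno, map)
tot <- total_ibd(merged)
cat("\nIBD segments:", nrow(ibd), "->", nrow(merged), "after merging;",
    nrow(tot), "pairs with shared segments\n")

l_tot <- sum(vapply(split(calls$windows, calls$windows$chrom),
                    function(w) max(w$egpos) - min(w$sgpos), 0))
rc <- race_concordance(tot, meta, cats, L_tot_cM = l_tot)
data.table::fwrite(rc$pairs, "results/pair_concordance.tsv", sep = "\t")
cat("\nrelated pairs (3rd degree or closer):", rc$summary$n_related,
    "| same race:", rc$summary$n_related_same_race,
    "| discordant race:", rc$summary$n_related_discordant_race, "\n")
cat(sprintf("discordant fraction: %.3f\n", rc$summary$discordant_fraction))
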