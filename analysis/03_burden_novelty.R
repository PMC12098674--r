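#!/usr/bin/env Rscript
# Local-ancestry-aware variant statistics: assign every alternate allele to
# the ancestry of its covering tract, flag rare deleterious / synonymous /
# novel variants, and compute per-ancestry burden, novelty counts (with the
# per-tract double-representation of admixed individuals) and the
# novel-vs-known impact enrichment.

suppressPackageStartupMessages(library(admixcohort))

geno <- read_phased_vcf("results/cohort/cohort.vcf")
calls <- read_msp("results/cohort/local_ancestry.msp.tsv")
ann <- read_annotations("results/cohort/annotations.tsv")

flags <- variant_flags(geno, ann)
cat(sprintf("variants: %d total, %.1f%% rare, %.1f%% novel, %d rare deleterious\n",
            nrow(geno$variants), 100 * mean(flags$rare), 100 * mean(flags$novel),
            sum(flags$rare & flags$deleterious)))

asn <- assign_alleles(geno, calls)
cat("alt alleles assigned:", unname(attr(asn, "coverage_report")["assigned"]),
    "; unassigned:", unname(attr(asn, "coverage_report")["unknown"]), "\n")

burden <- burden_by_ancestry(asn, flags, calls)
data.table::fwrite(burden, "results/burden_by_ancestry.tsv", sep = "\t")
agg <- stats::aggregate(cbind(per_gb_deleterious, del_syn_ratio) ~ ancestry,
                        data = burden[burden$tract_bp > 0, ], FUN = mean,
                        na.action = stats::na.omit)
cat("\nmean per-Gb rare-deleterious rate and del/syn ratio by ancestry segment:\n")
print(agg, row.names = FALSE)

props <- global_from_tracts(calls)
cats <- classify_ancestry(props)
nov <- novelty_by_group(geno, flags, cats)
nov_tract <- novelty_by_group(geno, flags, cats, per_tract = TRUE,
                              assignment = asn, proportions = props)
data.table::fwrite(nov, "results/novelty_by_individual.tsv", sep = "\t")
data.table::fwrite(nov_tract, "results/novelty_per_tract.tsv", sep = "\t")
cat("\nmean novel variants per individual by category:\n")
print(sort(tapply(nov$n_novel, nov$group, mean), decreasing = TRUE))

priv <- private_to_ancestry(asn, nrow(geno$variants))
cat("\nnovel variants private to one ancestry:",
    sum(!is.na(priv[flags$novel])), "of", sum(flags$novel), "\n")

enr <- impact_enrichment(flags, ann)
data.table::fwrite(enr, "results/impact_enrichment.tsv", sep = "\t")
cat("\nnovel-vs-known log odds ratio by impact (MODIFIER reference):\n")
print(enr[, c("impact", "beta", "se", "ci_low", "ci_high")], row.names = FALSE)
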