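#!/usr/bin/env Rscript
# Global ancestry from local-ancestry calls, discrete categorisation with
# the 85%/15% rules, zone composition and pairwise dissimilarity indices.
# Reads the files emitted by 01_simulate.R (the pipeline consumes exactly
# the on-disk formats, not the in-memory truth).

suppressPackageStartupMessages(library(admixcohort))

dir.create("results", showWarnings = FALSE)
calls <- read_msp("results/cohort/local_ancestry.msp.tsv")
meta <- read_metadata("results/cohort/metadata.tsv")

props <- global_from_tracts(calls)
cats <- classify_ancestry(props)
classes <- data.frame(sample = rownames(props), props,
                      category = unname(cats), check.names = FALSE)
data.table::fwrite(classes, "results/ancestry_categories.tsv", sep = "\t")

cat("category counts:\n")
print(sort(table(classes$category), decreasing = TRUE))

geo <- geo_params(min_zone_n = 20, min_category_n = 50)
comp <- zone_composition(cats, meta, geo)
data.table::fwrite(data.frame(zone = rownames(comp$proportions),
                              comp$proportions, check.names = FALSE),
                   "results/zone_composition.tsv", sep = "\t")
cat("\nzones dropped below the minimum size:",
    if (length(comp$dropped_zones)) paste(comp$dropped_zones, collapse = ", ")
    else "none", "\n")

dis <- dissimilarity_matrix(cats, meta, geo)
data.table::fwrite(dis, "results/dissimilarity.tsv", sep = "\t")
cat("\npairwise dissimilarity among large categories:\n")
print(dis[order(-dis$D), ], row.names = FALSE)
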