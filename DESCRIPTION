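Package: admixcohort
Title: Local-Ancestry-Aware Cohort Analysis for Admixed Biobanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing large admixed cohorts from phased genotypes
    and local-ancestry calls: discrete ancestry categorisation from global
    proportions, allele-to-tract ancestry assignment, rare deleterious and
    synonymous burden statistics by ancestry segment, novel-variant counts and
    impact enrichment, geographic stratification (zone composition and the
    dissimilarity index), disease prevalence and odds ratios with a
    Mantel-Haenszel random-condition reference panel, KING-robust kinship,
    IBD-segment post-processing, relationship-degree classification, and
    concordance between relatedness and self-reported race. Includes a
    synthetic admixed-cohort generator with known ground truth (tracts,
    pedigree relatives, race labels, zones, phenotypes) so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
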