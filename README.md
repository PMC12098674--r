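# admixcohort

Local-ancestry-aware analysis of admixed cohorts in R.

Large urban biobanks are genetically admixed: most participants carry
chromosomes that are mosaics of tracts from several continental
ancestries, and self-reported race aligns only loosely with that genetic
structure. Analysing such cohorts requires statistics that operate on the
tract level rather than on whole-genome labels. `admixcohort` implements
that analysis chain for phased genotypes plus window-based local-ancestry
calls (RFMix2-style `msp.tsv`):

* **Ancestry** — global proportions as the bp-weighted average of local
  calls; discrete categories by the threshold rules *single* (one
  component > 85%), *two-way* (two components ≥ 15% summing > 85%) and
  *multiway* (≥ 3 components > 15%); zone composition tables and the
  Duncan dissimilarity index
  `D = ½ Σ_z |a_z/A − b_z/B|` between categories.
* **Tract variants** — assignment of every alternate allele to the
  ancestry of its covering tract (half-open windows, `spos ≤ pos−1 <
  epos`); rare (cohort AF < 1%), deleterious (HIGH impact, or missense
  with SIFT < 0.05 and PolyPhen > 0.85), synonymous and novel
  (catalog-absent) flags; per-ancestry allele-level burden
  (deleterious/synonymous ratio, per-Gb rates), novel-variant counts with
  per-tract replication of admixed individuals, private-to-ancestry
  labels, and the novel-vs-known impact enrichment as the exact closed
  form of the logistic regression with MODIFIER reference
  (`β = log[(n_c/k_c)/(n_ref/k_ref)]`, `se = √Σ 1/cell`).
* **Disease** — Wald prevalence intervals; Woolf (log-OR-SE) odds-ratio
  intervals with Haldane–Anscombe correction; Mantel–Haenszel pooling with
  the Robins–Breslow–Greenland variance; and the comparison of target
  conditions against a pooled reference of 200 randomly sampled
  conditions under a non-White/White exposure dichotomy.
* **Relatedness** — KING-robust kinship
  `φ = (N_AaAa − 2N_AA,aa)/(N_Aa,i + N_Aa,j)`; hap-ibd-style segment
  merging (gap < 0.6 cM with ≤ 1 discordant homozygote); total IBD summed
  over haplotype channels; degree bins at 0.3536/0.1768/0.0884/0.0442;
  and concordance of related pairs with self-reported race.
* **Synthetic cohorts** — a generator with full ground truth (tracts from
  a 12-generation hybrid-isolation Poisson process, ancestry-specific
  allele frequencies, ancestry-biased catalog completeness, pedigree
  relatives with true IBD segments, race labels with configurable
  discordance, ancestry-stratified zones, ancestry/zone-linked disease
  risk), so every stage has a parameter-recovery test without any
  restricted data.

The methods vignette (`vignettes/admixed-cohort-methods.Rmd`) documents
the models, defaults and design decisions in detail.

## Worked example

Simulate a cohort, categorise it, and compare ancestry-linked conditions
against a random-condition reference:

```r
library(admixcohort)

cfg <- pipeline_config(sim = sim_config(n_samples = 600, n_variants = 5000),
                       seed = 4)
out <- run_pipeline(cfg)

table(out$classes$category)
#>        AFR    AFR-AMR    AFR-EAS        AMR        EAS    EAS-EUR        EUR
#>        158          1          3          1         18          7        140
#>    EUR-AFR    EUR-AMR   MULTIWAY UNASSIGNED
#>        140         66         56         42

out$geo$dissimilarity[1, ]
#>   category_a category_b        D
#> 1        AFR        EUR 0.663965

sort(tapply(out$novelty$by_individual$n_novel,
            out$novelty$by_individual$group, mean))[c("EUR", "AFR")]
#>      EUR      AFR
#> 35.92143 54.63291

out$disease$reference_panel$targets[1, c("condition", "or", "ci_low", "ci_high")]
#>   condition       or   ci_low  ci_high
#> 1    asthma 2.169437 1.251820 3.759691
```

Reading the output: half the cohort falls outside the single-ancestry
European category; European and African ancestry groups live in
substantially different zones (D = 0.66, where 0 is identical spatial
distribution and 1 complete segregation); individuals in the
underrepresented African-ancestry group carry ~1.5× more catalog-absent
variants per person than the European group, purely because the simulated
catalog is less complete for their ancestry; and the simulated
ancestry-linked asthma risk shows up as an odds ratio of 2.2 whose
confidence interval sits above the pooled Mantel–Haenszel reference of 200
null conditions (≈ 1.0).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow on files written to `results/cohort/` (simulate → ancestry/geo →
burden/novelty → disease → relatedness), printing what each stage found.

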