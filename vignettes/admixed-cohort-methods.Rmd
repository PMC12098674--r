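---
title: "Methods: local-ancestry-aware analysis of admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local-ancestry-aware analysis of admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixcohort)
```

# Scope

`admixcohort` re-implements, as a tested pipeline, the analysis chain used
to characterise large admixed biobank cohorts from phased genotypes and
window-based local-ancestry calls: discrete ancestry categorisation,
geographic stratification, allele-to-tract assignment with rare-variant
burden and novelty statistics, epidemiological comparisons against a
random-condition reference, and relatedness versus self-reported race.
Because cohorts of this kind are access-restricted, the package ships a
synthetic admixed-cohort generator with full ground truth; every stage is
validated by parameter recovery against that truth rather than against any
private data set.

Upstream inference is deliberately out of scope: we consume RFMix2-style
`msp.tsv` local-ancestry calls, VEP-style annotation tables, hap-ibd-style
IBD segments and pre-mapped phenotype tables; we do not run local-ancestry
inference, variant calling, phasing, annotation or EHR extraction.

# Models and procedures

## Discrete ancestry categories

Global ancestry is the bp-weighted fraction of each ancestry over both
haplotypes of the local-ancestry windows (a cM-weighted option exists; bp
is the default because msp windows carry bp bounds natively). Categories
follow threshold rules applied in order:

1. any component strictly above 85% gives that single-ancestry label;
2. otherwise, if the two largest components are each at least 15% and
   jointly above 85%, the pair label (recognised pairs such as `EUR-AFR`
   keep their conventional spelling; any other pair gets a systematic
   alphabetical `X-Y` label, so no information is lost);
3. otherwise, three or more components above 15% give `MULTIWAY`;
4. anything else is `UNASSIGNED`.

The `UNASSIGNED` class is our addition: vectors such as (0.84, 0.10, 0.06)
satisfy none of the printed rules, and we prefer flagging them to silently
forcing them into `MULTIWAY`. Rule (2) is restricted to the *top two*
components; with the default 85% joint threshold a third component of 15%
is arithmetically impossible, but the restriction matters when users lower
the thresholds. Inequality strictness matches the published wording
exactly (`>85%`, `at least 15%`, `over 85%`, `>15%`), and the test suite
pins the whole rule set against an independently coded brute-force oracle
on every 4-component proportion vector on a 0.01 grid.

## Geographic stratification

Zone composition tables drop zones below a minimum head count
(`min_zone_n`, published value 100) and the dissimilarity index

$$D = \tfrac12 \sum_z \left| \frac{a_z}{A} - \frac{b_z}{B} \right|$$

is computed between categories exceeding `min_category_n` (published value
500). Those defaults assume a five-figure cohort; the pipeline
configuration scales them (20 and 50) for the desk-scale synthetic cohort,
which is a cohort-size choice, not a change to the statistic.

## Allele-to-tract assignment and burden

Windows are half-open `[spos, epos)` in bp and the VCF position `pos` is
matched via `spos <= pos - 1 < epos`, so a variant exactly at a window's
end belongs to the following window and no allele is double-counted at
joins. Each alternate allele on a covered haplotype inherits its window's
ancestry; positions outside every window are reported `UNKNOWN` and
counted, never silently dropped.

Burden is allele-level — a homozygous alternate genotype contributes two
alleles — because haplotype assignment is intrinsically allele-level. The
deleterious rule is: HIGH impact, or missense with SIFT < 0.05 and
PolyPhen > 0.85 (PolyPhen oriented higher-is-damaging); synonymous by
consequence; rare means cohort alternate-allele frequency strictly below
1%, always computed from the analysis cohort itself with missing alleles
excluded from the denominator. Rates are per Gb of diploid tract length,
and the deleterious/synonymous ratio is reported per individual by default
(a pooled mode exists) since the published figure discusses distribution
peaks and spreads; it is missing, not zero, when the synonymous count is
zero. For novelty counts the per-tract mode replicates an admixed
individual once for every ancestry contributing at least 15% of the
genome, mirroring the published double representation of two-way admixed
groups, and counts distinct novel variants (variant-level) per individual.

## Impact enrichment

The novel-vs-known enrichment per impact class against the MODIFIER
reference is the exact closed form of a single-categorical-predictor
logistic regression:
$\beta_c = \log\frac{n_c/k_c}{n_{\mathrm{ref}}/k_{\mathrm{ref}}}$ with
$\mathrm{se} = \sqrt{\sum 1/\text{cell}}$, plus a Haldane–Anscombe 0.5 on
all four cells when any is zero. Tests require agreement with an
iteratively fitted `glm` to 1e-6 on random tables. Note that the synthetic
generator's catalog model depends only on a variant's origin ancestry, so
the generated cohorts carry *no* impact–novelty association and the
end-to-end enrichment is null by construction; the operation itself is
validated against the logistic oracle, not against a generative effect.

## Epidemiology

Prevalence uses the Wald interval truncated to [0, 1]; odds ratios use the
log-OR standard error (Woolf) interval, matching the published figure
legend, with the 0.5 correction on zero cells. The Mantel–Haenszel pooled
odds ratio uses the Robins–Breslow–Greenland variance; strata with an
empty margin are dropped and counted. The reference-panel comparison
samples `n_ref` (200) non-target conditions without replacement — with a
minimum case count filter (default 20; the desk-scale pipeline uses 5) —
builds one 2x2 table per condition against the non-White/White
self-report dichotomy, and pools them as the reference. Tests require
agreement with `metafor::rma.mh` and `stats::mantelhaen.test` to 1e-10.

## Relatedness

KING-robust kinship is
$\phi = (N_{AaAa} - 2N_{AA,aa}) / (N_{Aa}^{(i)} + N_{Aa}^{(j)})$ over
both-genotyped sites passing a cohort MAF filter (default > 0.01; an
LD-pruned site list can be supplied — pruning itself is not
re-implemented). IBD post-processing merges adjacent segments of a pair's
haplotype channel when the gap is shorter than 0.6 cM *and* contains at
most one opposite-homozygote site, iterating left-to-right to a fixpoint
(order-independent for sorted non-overlapping segments; the published
description does not state an order). Without genotypes only the gap rule
applies, with a warning.

Total IBD sums all four haplotype channels, so a monozygotic pair totals
twice the map length and the kinship-equivalent divisor is $4 L_{tot}$;
this convention differs across tools and is stated on every relevant
function. Degree bins use the standard powers-of-two cutpoints with the
published 0.0884 second/third-degree boundary; the value 0.0884 itself
falls in the third-degree bin because the published removal rule is
strictly below 0.0884.

# The synthetic cohort generator

The generator is first-class, tested code. Its model:

* **Tracts** — hybrid isolation: one admixture pulse `g = 12` generations
  ago, so breakpoints arrive as a Poisson process of rate `g` per Morgan
  and tract ancestries are i.i.d. in the individual's proportion vector.
  Visible switches are thinned to $gL(1 - \sum_k m_k^2)$, which the tests
  verify. There is no drift and no correlation between neighbouring tract
  labels — matching the generative assumption of the window-based LAI that
  the pipeline consumes, and keeping every expectation closed-form. A
  single `g` is used; per-individual admixture times are not modelled.
* **Admixture proportions** — a mixture of Dirichlet subcohorts chosen to
  resemble a southern-US urban biobank: AFR-dominant (30%), EUR-dominant
  (28%), AFR–EUR admixed (22%), EUR–AMR (10%), EAS (4%) and a diffuse
  component (6%).
* **Genotypes** — each variant gets one frequency per ancestry (Beta
  samplers; low-frequency parameters for HIGH/MODERATE/LOW variants,
  common-variant parameters for MODIFIER), an origin ancestry (argmax
  frequency, ties to the lowest code — deterministic so the catalog model
  is reproducible), and alleles drawn Bernoulli in the frequency of the
  tract covering each haplotype position. A `shared` frequency mode yields
  a structure-free null cohort for estimator calibration, and a
  `deleterious_ratio` hook scales deleterious-variant frequencies in one
  ancestry for burden-recovery experiments.
* **Catalog** — `known` is Bernoulli in a per-origin-ancestry completeness
  (default EUR 0.99, EAS 0.90, AFR 0.88, AMR 0.80), emulating the
  ancestry bias of reference catalogs.
* **Relatives** — founders get fresh tracts; gametes recombine with
  Poisson crossovers at 1 per Morgan; descendants inherit founder alleles
  through their recombination mosaics, and true IBD segments are the
  regions where two haplotypes descend from the same founder haplotype.
  Parent–offspring pairs therefore total exactly the map length under the
  channel-sum convention, which the tests assert exactly.
* **Metadata** — self-reported race is drawn from a per-category confusion
  row with discordance `d` (default 0.1) spread uniformly off the
  diagonal; zones draw from Dirichlet ancestry mixtures proportional to
  the individual's dominant ancestry; phenotypes are Bernoulli in a
  logistic model with intercept, per-category and per-zone effects, plus
  ~240 null conditions for the reference panel. 87% of individuals are
  under 18, matching the paediatric skew of the emulated cohort.

The same seed reproduces every emitted file byte-for-byte, and the emitted
msp file *is* the truth tract set, so the generator doubles as a perfect
local-ancestry oracle.

## What the generator does not emulate

Real data have linkage disequilibrium within ancestries, genotyping and
phasing error, local-ancestry miscalls, site-frequency spectra shaped by
demography and selection, correlated annotation errors, and
socially-structured (not conditionally-uniform) race misclassification.
Passing parameter-recovery tests therefore demonstrates that the
implementation computes the intended statistics, not that those statistics
are robust to real-world noise. In particular, published headline values
(0.67 EUR/AFR dissimilarity, beta = 0.95 enrichment, 771,717 novel
variants, 11.2% novel rate) arise from the access-restricted cohort and
are not reproduction targets at desk scale; the pipeline's checks are
property-based instead.

# Numerical choices and problem sizes

* Proportion vectors must sum to 1 within 1e-6; global-ancestry rows are
  exact by construction.
* The genetic map interpolates linearly between anchors and extrapolates
  with the terminal slope; a constant 1 cM/Mb fallback warns when no map
  is supplied. Intervals are half-open everywhere (msp windows, IBD
  segments, tracts).
* Multiallelic records are skipped, not split, and counted in a skip
  report, because the downstream statistics are framed on biallelic SNVs
  and splitting would make the cohort AF ambiguous. Missing genotypes are
  excluded from AF denominators and kinship site counts, never imputed as
  reference.
* Zero cells in 2x2 tables get the Haldane–Anscombe 0.5 on all four
  cells, flagged `corrected` in the output.
* Default test genome: two chromosomes of 10 Mb / 1 Morgan each with
  5,000 variants; the end-to-end cohort uses 600 unrelated individuals
  plus 16 pedigree pairs; kinship calibration uses a 35-chromosome,
  35-Morgan genome at 10,000 shared-frequency common variants; tract
  calibration uses 2,000 haplotypes. These sizes were chosen so each
  Monte-Carlo check retains a 3-standard-error margin while the entire
  suite stays interactive.
* At a 2-Morgan genome, KING-robust kinship for truly unrelated pairs has
  a standard deviation comparable to the 0.0442 third-degree boundary, so
  genome-wide kinship screens at desk scale show a tail of spurious
  third-degree calls; degree classification for the concordance analysis
  therefore uses total IBD on (merged) segments, and the kinship
  calibration tests use the 35-Morgan genome.

# Design decisions that were genuinely open

* **Pair labels**: unrecognised two-way combinations get systematic
  alphabetical labels rather than being collapsed; the published category
  list only needed `EUR-AFR` and `EUR-AMR`.
* **Renormalisation after dropping an ancestry** (the published analysis
  dropped a negligible reference group): supported via re-weighting the
  proportion matrix, off by default.
* **Fig-3d-style replication threshold**: the per-tract novelty mode uses
  the same 15% component threshold as classification, keeping one notion
  of "meaningful component" throughout.
* **msp input granularity**: one file may cover one or many chromosomes;
  the published pipeline's per-chromosome split is not stated.
* **Reference-condition pool**: whether the published 200 random
  conditions had a minimum case count is unstated; we filter (default 20)
  and log it.

# Limitations

Known limitations: no support for sex chromosomes or haploid regions; no
ancestry-adjusted kinship (REAP-style) — KING-robust only; IBD *detection*
is consumed, not performed; the reference-panel exposure dichotomy
(non-White vs White) is configurable but only binary; and the generator's
independence assumptions listed above. The published joint-PCA variance
figure and map rendering are out of scope.
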