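---
title: "Methods: seasonal diet profiles and trophic niche metrics from fecal metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal diet profiles and trophic niche metrics from fecal metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietniche)
```

## The analysis in one paragraph

`dietniche` analyses fecal DNA metabarcoding data from sympatric herbivores
— here a three-consumer design (sika deer, Reeves' muntjac, Chinese hare)
sampled over four seasons. The input is a post-clustering OTU count table,
a taxonomy assignment per OTU, and sample metadata. Read counts are
converted to relative read abundance (RRA), a semi-quantitative surrogate
for diet proportions; samples are pooled into one diet profile per
species × season; and those profiles feed the trophic niche statistics:
Levins' breadth $B = 1/\sum_i P_i^2$, Hurlbert's standardization
$B_a = (B-1)/(S-1)$, and Pianka's pairwise overlap
$Q_{jk} = \sum_i P_{ij}P_{ik} \big/ \sqrt{\sum_i P_{ij}^2 \sum_i P_{ik}^2}$,
with $Q > 0.6$ (strictly) read as a significant overlap. Around this core
the pipeline provides OTU-level alpha diversity with rarefaction and
Kruskal–Wallis comparisons, shared-OTU (Venn) partitions, Bray–Curtis
NMDS ordination with intra/intergroup distance analysis, and UPGMA
clustering.

## Assumptions

The niche statistics treat RRA as proportional resource use. That is an
approximation: amplification efficiency, chloroplast copy number and
differential digestion all distort read proportions relative to biomass
intake, and nothing in this package corrects for them. The statistics are
therefore comparative — between seasons and between consumers assayed
with the same marker and pipeline — rather than absolute diet estimates.

All group-level inference assumes samples are independent draws from the
group (no repeated sampling of one individual), and that the taxonomy
covers the marker's resolvable taxa; reads the classifier cannot place
are carried as "unassigned" and excluded from diet composition (OTU-level
statistics keep them).

## Taxonomy and consensus collapsing

Taxonomy rows are `otu_id<TAB>lineage` with a semicolon-separated lineage
ordered from the highest assigned rank downwards, mapped positionally
onto a configurable rank vector (default `kingdom … species`). A lineage
may stop early (missing lower ranks) but may not skip a rank — a filled
genus under an empty family is a format error. This is a declared
convention: classifier outputs vary, and a single explicit dialect keeps
round-trips bit-exact.

An OTU with several candidate lineages is collapsed to the deepest rank
shared by all candidates (two congeneric species → their genus; two
families in one order → the order); no candidates means unassigned. When
profiles are aggregated at, say, genus rank, an OTU resolved only to
family still contributes — under its family name — so assigned reads are
never silently discarded. Diet categories are therefore "taxa at or above
the analysis rank", which matches how mixed-rank diet tables are reported
in the field.

## RRA and pooling

Per sample, counts of OTUs mapping to the same taxon are summed and
divided by the sample's retained total, so each sample is a proportion
vector (sum-to-one enforced at $10^{-9}$). Two pooling rules turn ~30
samples into one group profile:

* `mean_rra` (default): the unweighted mean of per-sample proportion
  vectors. Each fecal sample counts equally; a deeply sequenced sample
  cannot dominate the seasonal profile. This follows the RRA literature's
  usual recommendation.
* `pooled_reads`: recompute proportions from summed counts, weighting
  samples by depth.

Both are implemented because published seasonal RRA percentages rarely
state which was used; the package asserts nothing about other studies'
choices. At the study's depths the two differ by little, but the default
is stated in every output manifest.

## The S convention in Hurlbert's standardization

$B_a = (B-1)/(S-1)$ needs a category count $S$. Here $S$ is the number of
taxa with nonzero RRA in that group's pooled profile — a per-consumer,
per-season count, not the global taxon universe and not the OTU count.
A global $S$ would make $B_a$ depend on what other groups ate, defeating
cross-season comparability. With $S = 1$, $B_a$ is 0 by convention.
Published breadth tables do not always back-compute under either
convention, so the convention used here is stated rather than
reverse-engineered from any particular table.

## Alpha diversity choices

* Shannon in natural log (nats); the base is configurable. Dietary
  diversity values of ~1.5–3 for profiles of tens to hundreds of items
  are the expected magnitudes in nats.
* Simpson is reported as Gini–Simpson $1-\sum p^2$ (the common default in
  amplicon workflows); the raw concentration $\sum p^2$ is available via
  `complement = FALSE`.
* Chao1 uses the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ everywhere: it is defined when no
  doubletons occur and never drops below observed richness.
* Pielou's evenness is $H/\ln S_{obs}$, defined as 1 for a one-taxon
  sample.
* Good's coverage is $1 - F_1/N$.
* Alpha diversity is computed on raw OTU counts including unassigned
  OTUs: OTU-level statistics describe sequencing output, before diet
  assignment decisions.

Rarefaction subsamples reads without replacement, 10 replicates per depth
with the median reported, and is seeded; at full depth it returns the
unrarefied index exactly. Group comparisons use the Kruskal–Wallis
rank-sum test (mid-ranks, tie-corrected H, $\chi^2_{k-1}$ reference);
all-identical values return $H = 0$, $p = 1$.

## Ordination, distances, clustering

Bray–Curtis dissimilarity is computed on per-sample RRA at the OTU level;
on proportion vectors it equals half the L1 distance, which is tested as
an invariant. NMDS minimizes Kruskal stress-1 with monotone regression
(via `vegan::monoMDS`), using one PCoA-initialized start plus random
restarts (20 total by default, tolerance $10^{-6}$ on the relative stress
ratio), returning the lowest-stress solution; results are bit-reproducible
for a given seed. On strongly clustered data (many between-group
dissimilarities saturated at 1) NMDS can reach near-zero stress through a
step-shaped monotone fit; stress values should be read alongside the
ordination plot, as in any NMDS workflow.

Intra/intergroup analysis splits the pairwise distances into within-group
and between-pair multisets, reports both medians and means (box-summary
conventions differ between publications), and tests each pair with
Kruskal–Wallis. UPGMA uses average-linkage `hclust`; the result is
ultrametric and serialized as Newick. Shared-OTU summaries call an OTU
present in a species when its summed seasonal reads reach 1 (after
excluding unassigned OTUs) and report the full 7-region Venn partition.

## The synthetic-data generator

`generate_dataset()` emulates the study design: 3 species × 4 seasons ×
30 fecal samples. Each group has a true genus-level diet profile $P^*$;
per sample a diet is drawn from $\mathrm{Dirichlet}(\alpha P^*)$
($\alpha = 50$ by default — fecal samples vary between individuals well
beyond counting noise), reads are drawn multinomially at a lognormal
depth (median 20,000 reads), each genus is split over 1–5 OTUs, ~20% of
OTUs carry two congeneric candidate lineages (so consensus collapsing is
actually exercised), and 10% of reads go to lineage-less OTUs.

True profiles are a dominant genus holding 42–68% of the diet plus a
geometric tail (ratio 0.9) over the remaining $S^*-1$ genera, with
$S^* = 18$–45 by species and season. The dominant-plus-tail shape mirrors
browse-dominated herbivore diets (one genus such as a bramble carrying
most reads, many minor items), and it keeps the mean-RRA estimator of
$B_a$ precise: a delta-method variance analysis of
$\hat{c} = \sum \hat{p}_i^2$ under Dirichlet-multinomial sampling shows
the estimator's standard error is driven by the dominant proportion, and
profiles without a dominant item would leave $\hat{B}_a$ too variable for
±0.02 truth recovery at these sample sizes. Seasonal structure encodes
browse phenology: summer pools are rich and relatively even (widest
niche), fall diets concentrate on the dominant genus (narrowest); the
hare-like consumer stays nearly constant year-round and feeds from the
opposite end of the resource pool, while the two ruminant-like consumers
share their dominant genus and most of their pool.

The truth object records $P^*$ and the exact $B^*$, $B_a^*$, $S^*$,
$Q^*_{jk}$ computed from it; the recovery suite regenerates data under
five seeds (depth $10^5$, 30 samples, $\alpha = 50$) and requires every
group's $B_a$ and every pair's $Q$ to land within ±0.02 of truth.

What the generator does **not** emulate: primer and amplification bias,
chimeras, reference-database gaps (unassigned reads are random here, not
taxonomically structured), copy-number variation, digestion-rate
differences, spatial/individual autocorrelation between samples, and
sequence-level artifacts. Passing recovery tests therefore validates the
statistical pipeline, not the wet-lab robustness of any particular study.

## Numerical conventions

* Proportion vectors must sum to 1 within $10^{-9}$; Pianka's $Q$ is
  clamped to $[0,1]$ against floating-point drift.
* Top-n tables break proportion ties alphabetically; the "Others" bucket
  preserves unit mass.
* The overlap significance rule is strict: $Q = 0.6$ exactly is not
  flagged.
* Growth-form lookup tries the taxon name, then climbs its lineage
  upward; unmatched mass is reported as `unknown`, never dropped.
* Every stochastic stage (rarefaction, NMDS, simulation) requires an
  explicit seed; the pipeline derives one stream per stage from its
  master seed so toggling stages leaves other results unchanged.

## Problem sizes

The shipped analysis scripts and the test suite run the full design (360
samples, 60-genus pool, median depth 20,000; depth $10^5$ in the recovery
suite) — the generator and estimators are cheap at this scale. Oracle
suites use $10^3$ random cases per statistic and $10^4$ for the Chao1
bound; NMDS examples use small exact configurations plus the 360-sample
ordination in the analysis scripts.

## Known limitations

* RRA-based breadth and overlap inherit all RRA biases; see Assumptions.
* $B_a$ comparisons across studies require the same $S$ convention.
* NMDS stress can be degenerate on saturated Bray–Curtis matrices.
* The taxonomy dialect is positional; inputs using rank-prefixed labels
  (`g__Rubus`) must be converted before reading.
* No null-model randomization of overlap and no PERMANOVA are provided;
  neither is part of this analysis design.
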