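# dietniche

Trophic niche analysis of herbivore diets from fecal DNA metabarcoding.

`dietniche` is for ecologists analysing diet composition of sympatric
herbivores from amplicon (e.g. trnL P6 loop) OTU tables. It takes a
post-clustering OTU count table, per-OTU taxonomy assignments and sample
metadata (species, season), and produces seasonal diet profiles and the
trophic-niche statistics used to ask whether co-occurring consumers
partition their food resources:

* **Relative read abundance (RRA)** diet profiles per species × season,
  after collapsing ambiguous OTU assignments to their lowest common
  taxonomic rank (two congeneric hits → the genus).
* **Levins' niche breadth** `B = 1 / Σᵢ Pᵢ²` and **Hurlbert's
  standardized breadth** `Ba = (B − 1)/(S − 1)` ∈ [0, 1], with `S` the
  number of food categories the group uses.
* **Pianka's niche overlap**
  `Q_jk = Σᵢ P_ij P_ik / √(Σᵢ P_ij² · Σᵢ P_ik²)` per species pair and
  season, with `Q > 0.6` (strict) flagged as significant overlap.
* OTU-level **alpha diversity** (Chao1, Shannon, Gini–Simpson, Pielou,
  Good's coverage), seeded median-of-10 **rarefaction curves**, and
  **Kruskal–Wallis** group comparisons.
* **Bray–Curtis** distances, seeded multi-restart **NMDS** ordination,
  intra/intergroup distance analysis, **UPGMA** clustering (Newick
  output), and shared-OTU **Venn** partitions.
* A **Dirichlet-multinomial synthetic-data generator** with analytically
  known niche truths, so the whole pipeline is testable end to end
  without any sequencing data.

The methods vignette (`vignettes/diet-niche-methods.Rmd`) documents the
statistical conventions (pooling rule, the `S` convention in `Ba`,
Shannon in nats, strict overlap threshold) and what the generator does
and does not emulate.

## Worked example

```r
library(dietniche)

# simulate the study design: 3 herbivores x 4 seasons x 30 fecal samples
cfg <- synthetic_config(seed = 1234)
ds  <- generate_dataset(cfg)

res <- run_pipeline(ds$table, ds$metadata, ds$taxonomy,
                    rank = "genus", stages = c("profiles", "niche"),
                    seed = 1234)
subset(res$niche$breadth, season == "fall")
#>           species season        B  S         Ba dietary_diversity
#> 7       sika_deer   fall 2.051842 20 0.05536008          1.476476
#> 8  reeves_muntjac   fall 2.227229 18 0.07218993          1.547685
#> 9    chinese_hare   fall 3.649669 36 0.07570484          2.214270
round(res$niche$overlap$fall$Q, 2)
#>                sika_deer reeves_muntjac chinese_hare
#> sika_deer           1.00           1.00            0
#> reeves_muntjac      1.00           1.00            0
#> chinese_hare        0.00           0.00            1
```

Reading: in fall both ruminant-like consumers concentrate on one dominant
genus (`B ≈ 2`, low `Ba`) and their diets overlap almost completely
(`Q = 1.00 > 0.6`, significant), while the hare-like consumer feeds from
a disjoint resource pool (`Q = 0`). Since the data are synthetic, every
estimate can be checked against the generator's truth
(`ds$truth$breadth`, `ds$truth$overlap`); with 30 samples at this depth
the estimated `Ba` land within ~0.01 of truth.

## Analysis workflow

The `analysis/` scripts run the whole study as a numbered pipeline,
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # synthetic dataset + truth table
Rscript analysis/02_alpha_diversity.R     # alpha diversity, KW tests, rarefaction
Rscript analysis/03_diet_profiles.R       # RRA profiles, top-10 genera, growth forms
Rscript analysis/04_community_structure.R # Venn, NMDS, distances, UPGMA
Rscript analysis/05_niche_metrics.R       # B, Ba, Q vs the known truth
```

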