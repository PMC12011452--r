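#!/usr/bin/env Rscript
# Stage 3: consensus taxonomy, RRA conversion and seasonal diet profiles.
#
# Collapses multi-candidate OTU assignments to their lowest common rank,
# converts counts to relative read abundance excluding unassigned OTUs,
# pools samples per species x season with equal weight (mean RRA), and
# tabulates the top-10 genera and growth-form composition per group.

library(dietniche)

tbl <- read_otu_table("results/data/otu_table.tsv")
md <- read_metadata("results/data/metadata.tsv", otu = tbl)
tax <- read_taxonomy("results/data/taxonomy.tsv",
                     ranks = c("family", "genus", "species"))
gf_map <- read_growth_forms("results/data/growth_forms.tsv")

res <- run_pipeline(tbl, md, tax, gf_map, rank = "genus",
                    stages = "profiles", seed = 1234L,
                    out_dir = "results")

resolved <- resolve_taxa(tax)
n_multi <- sum(lengths(tax) > 1L)
n_genus <- sum(vapply(resolved, function(l)
  !is.null(l) && names(l)[length(l)] == "genus", logical(1L)))
cat(sprintf("%d OTUs had multiple candidate taxa; %d resolved to genus by consensus\n",
            n_multi, n_genus))

for (g in c("sika_deer.fall", "chinese_hare.winter")) {
  cat("\nTop 5 genera,", g, ":\n")
  print(head(res$profiles$top_taxa[[g]], 5L))
}
cat("\nGrowth-form composition (sika deer, by season):\n")
for (se in DIET_SEASONS) {
  p <- res$profiles$growth_forms[[paste("sika_deer", se, sep = ".")]]
  cat(sprintf("  %-6s herb %.2f shrub %.2f arbor %.2f unknown %.2f\n",
              se, p["herb"], p["shrub"], p["arbor"], p["unknown"]))
}
cat("\nTables written: diet_profiles.tsv, top_taxa.tsv, growth_forms.tsv\n")
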