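test_that("consensus collapsing resolves ambiguity to the lowest shared rank", {
  # two congeneric species fall back to the genus
  cands <- list(c(family = "Rosaceae", genus = "Rubus",
                  species = "Rubus hirsutus"),
                c(family = "Rosaceae", genus = "Rubus",
                  species = "Rubus corchorifolius"))
  expect_equal(lca_collapse(cands),
               c(family = "Rosaceae", genus = "Rubus"))

  # a single candidate keeps its species rank
  one <- list(c(family = "Smilacaceae", genus = "Smilax",
                species = "Smilax china"))
  expect_equal(lca_collapse(one), one[[1L]])

  # different families within one order collapse to the order
  poales <- list(c(order = "Poales", family = "Poaceae", genus = "Poa"),
                 c(order = "Poales", family = "Cyperaceae",
                   genus = "Carex"))
  expect_equal(lca_collapse(poales), c(order = "Poales"))

  expect_null(lca_collapse(list()))
})

test_that("consensus collapsing equals a longest-common-prefix oracle on random lineages", {
  set.seed(41)
  for (i in 1:500) {
    k <- sample.int(4L, 1L)
    cands <- replicate(k, random_lineage(), simplify = FALSE)
    expect_identical(unname(lca_collapse(cands)),
                     unname(lcp_oracle(cands)) %||% NULL)
  }
})

test_that("RRA conversion sums OTUs per taxon and normalizes per sample", {
  tbl <- tiny_table()
  resolved <- resolve_taxa(tiny_taxonomy())
  rra <- to_rra(tbl, resolved, rank = "genus")
  # S1: Rubus (3+1)/8, Smilax 4/8
  expect_equal(rra["S1", "Rubus"], 0.5)
  expect_equal(rra["S1", "Smilax"], 0.5)
  expect_equal(rra["S2", "Rubus"], 0.25)
  expect_equal(unname(rowSums(rra)), c(1, 1), tolerance = 1e-12)
})

test_that("dropping unassigned reads renormalizes over assigned reads only", {
  m <- matrix(c(5L, 5L, 10L, 2L, 2L, 4L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("A", "B"), c("o1", "o2", "oU")))
  tbl <- otu_table(m)
  tax <- taxon_assignments(list(
    o1 = list(c(genus = "G1")), o2 = list(c(genus = "G2")),
    oU = list()), ranks = "genus")
  resolved <- resolve_taxa(tax)
  rra <- to_rra(tbl, resolved, rank = "genus", drop_unassigned = TRUE)
  expect_equal(rra["A", ], c(G1 = 0.5, G2 = 0.5))
  kept <- to_rra(tbl, resolved, rank = "genus", drop_unassigned = FALSE)
  expect_equal(kept["A", "unassigned"], 0.5)

  # a sample whose reads are all unassigned cannot be normalized
  m2 <- matrix(c(0L, 0L, 7L, 1L, 1L, 0L), nrow = 2L, byrow = TRUE,
               dimnames = list(c("A", "B"), c("o1", "o2", "oU")))
  expect_error(to_rra(otu_table(m2), resolved, rank = "genus"),
               "zero retained reads: A")
})

test_that("aggregating at a higher rank never increases the taxon count", {
  set.seed(7)
  cfg <- synthetic_config(seed = 11, samples_per_group = 3L)
  ds <- generate_dataset(cfg)
  resolved <- resolve_taxa(ds$taxonomy)
  for (pair in list(c("species", "genus"), c("genus", "family"))) {
    lo <- to_rra(ds$table, resolved, rank = pair[1L])
    hi <- to_rra(ds$table, resolved, rank = pair[2L])
    expect_lte(ncol(hi), ncol(lo))
    expect_equal(rowSums(hi), rowSums(lo), tolerance = 1e-9)
  }
})

test_that("group pooling matches hand arithmetic for both methods", {
  m <- matrix(c(9L, 1L, 0L, 10L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("oA", "oB")))
  tbl <- otu_table(m)
  tax <- taxon_assignments(list(oA = list(c(genus = "A")),
                                oB = list(c(genus = "B"))),
                           ranks = "genus")
  resolved <- resolve_taxa(tax)
  rra <- to_rra(tbl, resolved, rank = "genus")
  md <- sample_metadata(c("S1", "S2"), rep("sika_deer", 2),
                        rep("fall", 2))
  # equal-weight mean of {A:0.9,B:0.1} and {A:0,B:1}
  mean_p <- pool_group_profile(rra, md, "sika_deer", "fall")
  expect_equal(profile_sorted(mean_p), c(A = 0.45, B = 0.55))
  # pooled reads: (9+0)/20, (1+10)/20
  pooled <- pool_group_profile(rra, md, "sika_deer", "fall",
                               method = "pooled_reads", table = tbl,
                               resolved = resolved)
  expect_equal(profile_sorted(pooled), c(A = 0.45, B = 0.55))

  # per-depth weighting differs once depths are unequal
  m2 <- matrix(c(90L, 10L, 0L, 10L), nrow = 2L, byrow = TRUE,
               dimnames = list(c("S1", "S2"), c("oA", "oB")))
  tbl2 <- otu_table(m2)
  rra2 <- to_rra(tbl2, resolved, rank = "genus")
  p_mean <- pool_group_profile(rra2, md, "sika_deer", "fall")
  p_pool <- pool_group_profile(rra2, md, "sika_deer", "fall",
                               method = "pooled_reads", table = tbl2,
                               resolved = resolved)
  expect_equal(profile_sorted(p_mean)[["A"]], 0.45)
  expect_equal(profile_sorted(p_pool)[["A"]], 90 / 110)

  expect_error(pool_group_profile(rra, md, "chinese_hare", "fall"),
               "no samples")
})

test_that("mean-RRA pooling is invariant under sample reordering", {
  set.seed(5)
  cfg <- synthetic_config(seed = 3, samples_per_group = 6L)
  ds <- generate_dataset(cfg)
  resolved <- resolve_taxa(ds$taxonomy)
  rra <- to_rra(ds$table, resolved, rank = "genus")
  p1 <- pool_group_profile(rra, ds$metadata, "sika_deer", "summer")
  perm <- sample(nrow(rra))
  rra_p <- rra[perm, , drop = FALSE]
  attributes(rra_p)[c("rank", "lineages")] <-
    attributes(rra)[c("rank", "lineages")]
  class(rra_p) <- class(rra)
  p2 <- pool_group_profile(rra_p, ds$metadata, "sika_deer", "summer")
  expect_equal(profile_sorted(p1), profile_sorted(p2), tolerance = 1e-12)
})

test_that("top-n ranks by proportion with alphabetical tie-break and Others remainder", {
  p <- diet_profile(c(A = 0.5, B = 0.3, C = 0.2), rank = "genus")
  all3 <- top_n_taxa(p, 10L)
  expect_equal(all3$taxon, c("A", "B", "C"))
  top2 <- top_n_taxa(p, 2L)
  expect_equal(top2$taxon, c("A", "B", "Others"))
  expect_equal(sum(top2$proportion), 1)
  expect_equal(top2$proportion[3L], 0.2)

  tie <- diet_profile(c(B = 0.4, A = 0.4, C = 0.2), rank = "genus")
  expect_equal(top_n_taxa(tie, 1L)$taxon[1L], "A")
})

test_that("growth-form composition sums diet mass by form with lineage fallback", {
  lin <- list(Rubus = c(family = "Rosaceae", genus = "Rubus"),
              Poa = c(family = "Poaceae", genus = "Poa"),
              Mystery = c(family = "Unknowniaceae", genus = "Mystery"))
  p <- diet_profile(c(Rubus = 0.6, Poa = 0.3, Mystery = 0.1),
                    rank = "genus", lineages = lin)
  map <- growth_form_map(c("Rubus", "Poaceae"), c("shrub", "herb"))
  gf <- growth_form_percentages(p, map)
  expect_equal(gf[["shrub"]], 0.6)   # direct genus hit
  expect_equal(gf[["herb"]], 0.3)    # family-level fallback
  expect_equal(gf[["unknown"]], 0.1) # unmapped
  expect_equal(sum(gf), 1)
})

test_that("profiles and per-sample RRA conserve unit mass", {
  cfg <- synthetic_config(seed = 19, samples_per_group = 4L)
  ds <- generate_dataset(cfg)
  resolved <- resolve_taxa(ds$taxonomy)
  rra <- to_rra(ds$table, resolved, rank = "genus")
  expect_true(all(abs(rowSums(rra) - 1) < 1e-9))
  p <- pool_group_profile(rra, ds$metadata, "chinese_hare", "winter")
  expect_equal(sum(p$proportions), 1, tolerance = 1e-9)
  expect_true(all(p$proportions > 0 & p$proportions <= 1))
})
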