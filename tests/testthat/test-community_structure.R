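test_that("Bray-Curtis matches hand arithmetic and its boundary cases", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "both vectors are zero")
  expect_error(bray_curtis(c(1, -1), c(1, 1)), "negative")
})

test_that("on proportion vectors Bray-Curtis equals half the L1 distance", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(2:20, 1L)
    x <- stats::rgamma(n, 1); x <- x / sum(x)
    y <- stats::rgamma(n, 1); y <- y / sum(y)
    expect_equal(bray_curtis(x, y), sum(abs(x - y)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("the distance matrix agrees with vegdist", {
  set.seed(29)
  m <- matrix(stats::rpois(60, 10), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
  D <- bray_curtis_matrix(m)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], bray_curtis(m[i, ], m[j, ]), tolerance = 1e-12)
  expect_equal(unname(diag(D)), rep(0, 6))
})

test_that("NMDS recovers a perfectly embeddable planar configuration", {
  pts <- matrix(c(0, 0, 1, 0, 0.2, 1.3, 1.1, 0.9), ncol = 2, byrow = TRUE)
  rownames(pts) <- paste0("p", 1:4)
  D <- as.matrix(stats::dist(pts))
  ord <- nmds(D, dims = 2L, n_restarts = 3L, seed = 5)
  expect_lt(ord$stress, 1e-6)
  # configuration matches up to rotation/reflection/scale
  pr <- vegan::procrustes(pts, ord$coordinates, symmetric = TRUE)
  expect_lt(sum(pr$X - pr$Yrot)^2, 1e-4)
  expect_lt(summary(pr)$rmse, 1e-4)
})

test_that("NMDS is deterministic for a fixed seed and errors on bad input", {
  set.seed(3)
  D <- random_distance(10L)
  a <- nmds(D, seed = 42, n_restarts = 5L)
  b <- nmds(D, seed = 42, n_restarts = 5L)
  expect_identical(a$stress, b$stress)
  expect_identical(a$coordinates, b$coordinates)
  D2 <- D; D2[1, 2] <- D2[1, 2] + 0.1
  expect_error(nmds(D2, seed = 1), "symmetric")
  expect_error(nmds(D, n_restarts = 2L), "seed")
})

test_that("two points embed with zero stress", {
  D <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  ord <- nmds(D, dims = 2L, n_restarts = 2L, seed = 1)
  expect_lt(ord$stress, 1e-9)
  expect_equal(dim(ord$coordinates), c(2L, 2L))
})

test_that("intra/intergroup distances split the distance multiset correctly", {
  set.seed(12)
  # two tight far-apart clusters: between-median exceeds within-medians
  pts <- rbind(matrix(stats::rnorm(10, 0, 0.05), ncol = 2),
               matrix(stats::rnorm(10, 5, 0.05), ncol = 2))
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  labels <- rep(c("g1", "g2"), each = 5L)
  ig <- intergroup_distances(D, labels)
  expect_length(ig$within$g1, choose(5, 2))
  expect_length(ig$between[["g1 vs g2"]], 25L)
  btw <- ig$summary$median[ig$summary$type == "between"]
  expect_true(all(btw > ig$summary$median[ig$summary$type == "within"]))
  expect_equal(nrow(ig$tests), 1L)
  expect_lt(ig$tests$p_value, 0.05)

  # permuting samples within a group leaves the multisets unchanged
  perm <- c(sample(1:5), 6:10)
  ig2 <- intergroup_distances(D[perm, perm], labels)
  expect_equal(sort(ig2$within$g1), sort(ig$within$g1))
  expect_equal(sort(ig2$between[["g1 vs g2"]]),
               sort(ig$between[["g1 vs g2"]]))

  # all-identical samples give all-zero distances
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  igz <- intergroup_distances(Z, c("a", "a", "b", "b"))
  expect_true(all(unlist(igz$within) == 0))
  expect_true(all(unlist(igz$between) == 0))

  # singleton groups are flagged, not an error
  igs <- intergroup_distances(D[1:6, 1:6], c(rep("g1", 5), "g2"))
  expect_equal(igs$singleton_groups, "g2")
})

test_that("UPGMA yields the textbook trees on tiny inputs", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(D2)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))

  D3 <- matrix(0.8, 3, 3, dimnames = list(c("A", "B", "C"),
                                          c("A", "B", "C")))
  D3["A", "B"] <- D3["B", "A"] <- 0.2
  diag(D3) <- 0
  hc <- attr(upgma(D3), "hclust")
  expect_equal(sort(hc$labels[-hc$merge[1L, ]]), c("A", "B"))
  expect_equal(hc$height, c(0.2, 0.8))
})

test_that("UPGMA matches a naive agglomeration oracle and is ultrametric", {
  set.seed(47)
  for (i in 1:50) {
    D <- random_distance(6L)
    tr <- upgma(D)
    hc <- attr(tr, "hclust")
    coph <- as.matrix(stats::cophenetic(hc))
    oracle <- upgma_cophenetic_oracle(D)
    expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
    # ultrametric: root-to-leaf depths all equal
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_lt(max(depths) - min(depths), 1e-12)
  }
})

test_that("shared-OTU counts partition presence into Venn regions", {
  # presence sets {A,B}, {B,C}, {B} over species
  m <- matrix(c(3L, 5L, 0L,
                0L, 2L, 4L,
                0L, 7L, 0L), nrow = 3L, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("A", "B", "C")))
  tbl <- otu_table(m)
  md <- sample_metadata(c("s1", "s2", "s3"), DIET_SPECIES, rep("fall", 3))
  v <- shared_otu_counts(tbl, md, "fall")
  expect_equal(v$shared_all, 1L)  # only OTU B everywhere
  expect_equal(unname(v$specific), c(1L, 1L, 0L))  # A and C are private
  expect_equal(v$total, 3L)
  expect_equal(sum(v$regions), v$total)

  # identical presence puts every OTU in the shared-by-all region
  m2 <- matrix(rep(c(1L, 2L, 3L), 3), nrow = 3L, byrow = TRUE,
               dimnames = dimnames(m))
  v2 <- shared_otu_counts(otu_table(m2), md, "fall")
  expect_equal(v2$shared_all, 3L)

  # disjoint sets: shared 0, specifics equal the set sizes
  m3 <- diag(c(5L, 5L, 5L))
  dimnames(m3) <- dimnames(m)
  v3 <- shared_otu_counts(otu_table(m3), md, "fall")
  expect_equal(v3$shared_all, 0L)
  expect_equal(unname(v3$specific), c(1L, 1L, 1L))

  expect_error(shared_otu_counts(tbl, md, "spring"), "season")
})
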