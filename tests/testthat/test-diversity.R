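test_that("chao1 follows the bias-corrected estimator", {
  expect_equal(chao1(c(1, 1, 2, 3)), 4.5)        # 4 + 2*1/(2*2)
  expect_equal(chao1(c(2, 3, 4)), 3)             # no singletons
  expect_equal(chao1(1), 1)
  expect_error(chao1(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "non-negative integers")
})

test_that("chao1 never falls below observed richness", {
  set.seed(23)
  for (i in 1:2000) {
    x <- stats::rpois(sample(3:40, 1L), lambda = stats::runif(1, 0.5, 5))
    if (sum(x) == 0) next
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("shannon, simpson and pielou hit their closed forms", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(1), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0.7, -0.2, 0.5)), "negative")

  expect_equal(simpson(rep(0.25, 4)), 0.75)
  expect_equal(simpson(1), 0)
  expect_equal(simpson(rep(0.25, 4), complement = FALSE), 0.25)

  expect_equal(pielou(rep(0.2, 5)), 1)
  expect_equal(pielou(1), 1)  # single-category convention

  # uniform identities over random support sizes
  for (S in c(2L, 7L, 31L)) {
    expect_equal(shannon(rep(1 / S, S)), log(S))
    expect_equal(simpson(rep(1 / S, S)), 1 - 1 / S)
    expect_equal(pielou(rep(1 / S, S)), 1)
  }
})

test_that("Good's coverage is 1 - F1/N", {
  expect_equal(goods_coverage(c(1, 2, 3)), 1 - 1 / 6)
  expect_equal(goods_coverage(c(5, 5)), 1)
  expect_equal(goods_coverage(c(1, 1)), 0)
})

test_that("alpha diversity table respects its invariants on synthetic data", {
  cfg <- synthetic_config(seed = 2, samples_per_group = 3L)
  ds <- generate_dataset(cfg)
  a <- alpha_diversity(ds$table)
  expect_equal(nrow(a), nrow(ds$table))
  expect_true(all(a$chao1 >= a$observed_otus))
  expect_true(all(a$shannon >= 0))
  expect_true(all(a$pielou >= 0 & a$pielou <= 1))
  expect_true(all(a$goods_coverage >= 0 & a$goods_coverage <= 1))
  expect_true(all(a$simpson >= 0 & a$simpson < 1))
})

test_that("rarefaction at full depth reproduces the unrarefied index exactly", {
  x <- c(12L, 5L, 3L, 1L, 1L)
  rc <- rarefaction_curve(x, depths = c(5L, sum(x)), n_replicates = 3L,
                          seed = 99)
  expect_equal(rc$value[rc$depth == sum(x)], shannon(x, counts = TRUE))
  # single-OTU sample has zero entropy at any depth
  rc1 <- rarefaction_curve(c(40L), depths = c(10L, 40L), seed = 1)
  expect_equal(rc1$value, c(0, 0))
  expect_error(rarefaction_curve(x, depths = 1000L, seed = 1),
               "exceeds sample total")
  expect_error(rarefaction_curve(x, depths = 5L), "requires a seed")
})

test_that("median rarefied Shannon of an even two-OTU sample stays near ln 2", {
  rc <- rarefaction_curve(c(500L, 500L), depths = 100L,
                          n_replicates = 10L, seed = 4)
  expect_lt(abs(rc$value - log(2)), 0.05)
})

test_that("rarefaction curves are reproducible from the seed", {
  x <- c(30L, 20L, 10L, 5L)
  a <- rarefaction_curve(x, depths = c(10L, 30L), seed = 77)
  b <- rarefaction_curve(x, depths = c(10L, 30L), seed = 77)
  expect_identical(a, b)
})

test_that("Kruskal-Wallis matches hand rank arithmetic and handles ties", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 4.5714, tolerance = 1e-4)
  expect_equal(kw$df, 2L)

  flat <- kruskal_wallis(list(c(1, 1), c(1, 1)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # permuting labels with the same partition sizes leaves H unchanged
  set.seed(31)
  x <- stats::rnorm(12)
  h1 <- kruskal_wallis(list(x[1:4], x[5:8], x[9:12]))$statistic
  perm <- sample(12)
  h_vals <- kruskal_wallis(list(x[perm[1:4]], x[perm[5:8]],
                                x[perm[9:12]]))
  expect_equal(sort(rank(x)), 1:12)
  expect_equal(kruskal_wallis(list(x[1:4], x[5:8], x[9:12]))$statistic, h1)
})

test_that("Kruskal-Wallis H equals the tie-corrected oracle on random inputs", {
  set.seed(11)
  for (i in 1:300) {
    k <- sample(2:4, 1L)
    groups <- lapply(seq_len(k), function(j)
      sample(1:6, sample(2:6, 1L), replace = TRUE))
    if (length(unique(unlist(groups))) == 1L) next
    expect_equal(kruskal_wallis(groups)$statistic, kw_oracle(groups),
                 tolerance = 1e-10)
  }
})
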