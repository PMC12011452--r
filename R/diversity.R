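#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + F1(F1 - 1) / (2(F2 + 1))`, with F1 the number of singleton and
#' F2 the number of doubleton OTUs. The bias-corrected form is defined even
#' when no doubletons occur and never falls below the observed richness.
#'
#' @param counts non-negative integer read counts of one sample.
#' @return Estimated richness (>= observed number of OTUs).
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon-Wiener diversity index
#'
#' `-sum(p * log(p))` over positive proportions; natural log by default so
#' the maximum for S categories is `log(S)` nats.
#'
#' @param p proportion vector summing to 1 (within 1e-9), or a count vector
#'   when `counts = TRUE`.
#' @param base logarithm base (default `exp(1)`).
#' @param counts treat `p` as counts and normalize first?
#' @return Shannon index, >= 0.
#' @export
shannon <- function(p, base = exp(1), counts = FALSE) {
  p <- check_proportions(p, counts = counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Simpson diversity (Gini-Simpson, 1 - sum p^2)
#'
#' @inheritParams shannon
#' @param complement return `1 - sum(p^2)` (default); `FALSE` returns the
#'   raw concentration `sum(p^2)`.
#' @export
simpson <- function(p, counts = FALSE, complement = TRUE) {
  p <- check_proportions(p, counts = counts)
  d <- sum(p^2)
  if (complement) 1 - d else d
}

#' Pielou's evenness
#'
#' Shannon index over its maximum `log(S_obs)`; defined as 1 for a
#' single-category sample.
#'
#' @inheritParams shannon
#' @export
pielou <- function(p, counts = FALSE) {
  p <- check_proportions(p, counts = counts)
  s_obs <- sum(p > 0)
  if (s_obs == 1L) return(1)
  shannon(p) / log(s_obs)
}

#' Good's coverage
#'
#' `1 - F1/N`: the estimated fraction of reads belonging to OTUs already
#' observed more than once.
#'
#' @param counts non-negative integer read counts of one sample.
#' @export
goods_coverage <- function(counts) {
  counts <- check_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("all-zero count vector")
  round(counts)
}

check_proportions <- function(p, counts = FALSE) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("negative entries in proportion/count vector")
  if (counts) {
    if (sum(p) == 0) stop("all-zero count vector")
    return(p / sum(p))
  }
  if (abs(sum(p) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  p
}

#' Per-sample alpha-diversity table
#'
#' One row per sample: observed OTUs, Chao1, Shannon (nats), Gini-Simpson,
#' Pielou evenness and Good's coverage, computed on raw OTU counts
#' (unassigned OTUs included, as OTU-level statistics precede diet
#' assignment).
#'
#' @param table an [otu_table()].
#' @return data.frame keyed by sample_id.
#' @export
alpha_diversity <- function(table) {
  m <- unclass(table)
  res <- lapply(rownames(m), function(s) {
    x <- m[s, ]
    data.frame(sample_id = s,
               observed_otus = sum(x > 0),
               chao1 = chao1(x),
               shannon = shannon(x, counts = TRUE),
               simpson = simpson(x, counts = TRUE),
               pielou = pielou(x, counts = TRUE),
               goods_coverage = goods_coverage(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rarefaction curve of a diversity index
#'
#' At each depth, reads are subsampled without replacement
#' `n_replicates` times and the median index value is reported
#' (10 replicates with the median by default).
#'
#' @param counts OTU counts of one sample.
#' @param depths increasing read depths, each <= the sample total.
#' @param n_replicates subsamples per depth.
#' @param index `"shannon"`, `"observed"`, `"chao1"` or `"simpson"`.
#' @param seed RNG seed (required: curves are stochastic).
#' @return data.frame of class `rarefaction_curve` with columns depth,
#'   value; attributes `index`, `n_replicates`, `seed`.
#' @export
rarefaction_curve <- function(counts, depths, n_replicates = 10L,
                              index = c("shannon", "observed", "chao1",
                                        "simpson"),
                              seed) {
  index <- match.arg(index)
  counts <- check_counts(counts)
  if (missing(seed)) stop("rarefaction_curve requires a seed")
  depths <- sort(unique(as.integer(depths)))
  if (any(depths <= 0)) stop("depths must be positive")
  if (any(depths > sum(counts)))
    stop("depth exceeds sample total (", sum(counts), ")")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  fn <- switch(index,
               shannon = function(x) shannon(x, counts = TRUE),
               observed = function(x) sum(x > 0),
               chao1 = chao1,
               simpson = function(x) simpson(x, counts = TRUE))
  set.seed(seed)
  vals <- vapply(depths, function(d) {
    reps <- vapply(seq_len(n_replicates), function(i) {
      # counts are validated integers; rrarefy's "observed counts"
      # heuristic warning is spurious here
      sub <- suppressWarnings(vegan::rrarefy(counts, d))
      fn(as.numeric(sub))
    }, numeric(1L))
    stats::median(reps)
  }, numeric(1L))
  structure(data.frame(depth = depths, value = vals),
            index = index, n_replicates = n_replicates, seed = seed,
            class = c("rarefaction_curve", "data.frame"))
}

#' Kruskal-Wallis rank-sum comparison of index values across groups
#'
#' Mid-rank handling of ties with the tie-corrected H statistic and a
#' chi-square reference distribution on k - 1 degrees of freedom. When all
#' values are identical H is 0 and p is 1.
#'
#' @param groups list of >= 2 numeric vectors (one per group).
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs a list of >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(x) < 3L) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Alpha-diversity group comparison table
#'
#' Applies [kruskal_wallis()] to each diversity index across the levels of
#' a grouping factor (e.g. species within one season).
#'
#' @param alpha output of [alpha_diversity()].
#' @param metadata `sample_metadata`.
#' @param by `"species"` or `"season"`.
#' @return data.frame with one row per index: statistic, p_value.
#' @export
compare_alpha_diversity <- function(alpha, metadata, by = "species") {
  md <- metadata[match(alpha$sample_id, metadata$sample_id), ]
  idx <- c("observed_otus", "chao1", "shannon", "simpson", "pielou")
  res <- lapply(idx, function(i) {
    grp <- split(alpha[[i]], droplevels(md[[by]]))
    kw <- kruskal_wallis(grp)
    data.frame(index = i, statistic = kw$statistic, p_value = kw$p_value)
  })
  do.call(rbind, res)
}
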