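#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, in \[0, 1\]: 0 for
#' identical vectors, 1 for disjoint supports. On proportion vectors this
#' equals half the L1 distance.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @export
bray_curtis <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("vectors of unequal length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  if (sum(x) + sum(y) == 0) stop("both vectors are zero")
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Bray-Curtis distance matrix over samples
#'
#' Pairwise dissimilarities via [vegan::vegdist()].
#'
#' @param m samples x features abundance matrix (counts or RRA).
#' @return A symmetric `dist`-backed matrix of class `distance_matrix`
#'   with zero diagonal.
#' @export
bray_curtis_matrix <- function(m) {
  m <- as.matrix(m)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  distance_matrix(d)
}

#' Validate a distance matrix
#' @param D square symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix diagonal must be 0")
  if (any(D < 0)) stop("negative distances")
  structure(D, class = c("distance_matrix", "matrix", "array"))
}

#' Nonmetric multidimensional scaling on a distance matrix
#'
#' Kruskal's NMDS: iterative stress minimization with monotone regression
#' on dissimilarity ranks, delegated to [vegan::monoMDS()]. One restart is
#' initialized from principal-coordinates (PCoA) axes and the remainder
#' from random configurations; the lowest-stress solution is returned.
#' Deterministic for a given seed.
#'
#' @param D a [distance_matrix()] (or square symmetric matrix).
#' @param dims embedding dimension (default 2).
#' @param n_restarts total starts (1 PCoA + the rest random).
#' @param max_iter,tol iteration cap and relative stress-change tolerance
#'   per start.
#' @param seed RNG seed (required).
#' @return Object of class `ordination_result`: list with `ids`,
#'   `coordinates` (n x dims), `stress` (Kruskal stress-1), `converged`,
#'   `n_restarts`, `seed`.
#' @export
nmds <- function(D, dims = 2L, n_restarts = 20L, max_iter = 300L,
                 tol = 1e-6, seed) {
  if (missing(seed)) stop("nmds requires a seed")
  D <- distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 points")
  # n points always embed in n-1 dimensions; extra axes are zero-padded
  k <- min(dims, n - 1L)
  d <- stats::as.dist(D)
  set.seed(seed)
  init <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(init) < k)
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    y0 <- if (r == 1L) init else matrix(stats::runif(n * k, -1, 1), n)
    fit <- try(vegan::monoMDS(d, y = y0, k = k, model = "global",
                              maxit = max_iter, smin = 1e-9,
                              sfgrmin = 1e-10, sratmax = 1 - tol),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("all NMDS restarts failed")
  coords <- best$points
  if (ncol(coords) < dims)
    coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
  dimnames(coords) <- list(rownames(D), paste0("NMDS", seq_len(dims)))
  structure(list(ids = rownames(D), coordinates = coords,
                 stress = best$stress,
                 converged = best$icause != 1L,  # 1 = hit iteration cap
                 n_restarts = n_restarts, seed = seed),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points, %d axes, stress = %.4g\n",
              length(x$ids), ncol(x$coordinates), x$stress))
  invisible(x)
}

#' Within- and between-group sample distances
#'
#' Splits the pairwise distances by group labels into within-group
#' multisets (one per group) and between-group multisets (one per pair),
#' summarizes each with its median and mean, and tests each group pair
#' (within-j, within-k, between-jk) with [kruskal_wallis()].
#'
#' @param D a [distance_matrix()].
#' @param labels group label per sample (recycled against `rownames(D)`).
#' @return list with `within` (named list of numeric vectors), `between`
#'   (named list per pair), `summary` (data.frame: type, group, median,
#'   mean, n) and `tests` (data.frame per pair with H and p).
#' @export
intergroup_distances <- function(D, labels) {
  D <- distance_matrix(D)
  labels <- as.character(labels)
  if (length(labels) != nrow(D)) stop("one label per sample required")
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need >= 2 groups")
  idx <- split(seq_along(labels), labels)[groups]
  pick_upper <- function(i, j) {
    if (identical(i, j)) {
      if (length(i) < 2L) return(numeric(0))
      cb <- t(utils::combn(i, 2L))
    } else {
      cb <- as.matrix(expand.grid(i = i, j = j))
    }
    D[cb]
  }
  within <- lapply(idx, function(i) pick_upper(i, i))
  singletons <- names(within)[lengths(within) == 0L]
  between <- list()
  tests <- NULL
  for (a in seq_len(length(groups) - 1L)) for (b in (a + 1L):length(groups)) {
    ga <- groups[a]; gb <- groups[b]
    key <- paste(ga, gb, sep = " vs ")
    between[[key]] <- pick_upper(idx[[ga]], idx[[gb]])
    if (length(within[[ga]]) > 0L && length(within[[gb]]) > 0L) {
      kw <- kruskal_wallis(list(within[[ga]], within[[gb]],
                                between[[key]]))
      tests <- rbind(tests, data.frame(pair = key, H = kw$statistic,
                                       p_value = kw$p_value))
    }
  }
  summarize <- function(x, type, group)
    data.frame(type = type, group = group,
               median = if (length(x)) stats::median(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               n = length(x))
  summ <- rbind(
    do.call(rbind, Map(summarize, within, "within", names(within))),
    do.call(rbind, Map(summarize, between, "between", names(between))))
  rownames(summ) <- NULL
  list(within = within, between = between, summary = summ, tests = tests,
       singleton_groups = singletons)
}

#' UPGMA hierarchical clustering
#'
#' Average-linkage agglomeration of a distance matrix into an ultrametric
#' rooted tree (every root-to-leaf path has equal length).
#'
#' @param D a [distance_matrix()].
#' @return An [ape::as.phylo()] tree (class `phylo`), with the `hclust`
#'   merge structure attached as attribute `hclust`.
#' @export
upgma <- function(D) {
  D <- distance_matrix(D)
  if (nrow(D) < 2L) stop("need >= 2 leaves")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` tree.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Shared and specific OTU counts across species within a season
#'
#' An OTU is "present" for a species when its summed reads across that
#' species' samples in the season reach `presence_threshold`. Unassigned
#' OTUs can be excluded first (the default, matching the exclusion of
#' unclassified sequences before Venn analysis). Returns the 7-region Venn
#' partition for the three species plus the per-species specific counts
#' and the shared-by-all count.
#'
#' @param table an [otu_table()].
#' @param metadata `sample_metadata`.
#' @param season season to analyse.
#' @param resolved optional resolved taxonomy ([resolve_taxa()]); when
#'   given, OTUs resolving to `NULL` are excluded.
#' @param presence_threshold minimum summed reads (default 1).
#' @return Object of class `shared_otu_summary`: list with `season`,
#'   `species`, `regions` (named integer vector over the 7 membership
#'   patterns such as `"sika_deer"`, `"sika_deer+chinese_hare"`, ...),
#'   `specific` (per species), `shared_all`, `total`.
#' @export
shared_otu_counts <- function(table, metadata, season, resolved = NULL,
                              presence_threshold = 1L) {
  md <- metadata[metadata$season == season, ]
  species <- levels(droplevels(md$species))
  if (length(species) < 1L || !all(table(droplevels(md$species)) > 0))
    stop("every species needs >= 1 sample in season ", season)
  m <- unclass(table)
  if (!is.null(resolved)) {
    assigned <- colnames(m)[!vapply(colnames(m), function(o)
      is.null(resolved[[o]]), logical(1L))]
    m <- m[, assigned, drop = FALSE]
  }
  present <- sapply(species, function(sp) {
    ids <- intersect(md$sample_id[md$species == sp], rownames(m))
    if (length(ids) == 0L) stop("species ", sp, " missing in season ", season)
    colSums(m[ids, , drop = FALSE]) >= presence_threshold
  })
  pattern <- apply(present, 1L, function(r)
    paste(species[r], collapse = "+"))
  pattern <- pattern[nzchar(pattern)]
  regions <- table(pattern)
  regions <- stats::setNames(as.integer(regions), names(regions))
  shared_all <- sum(rowSums(present) == length(species))
  specific <- vapply(species, function(sp)
    sum(present[, sp] & rowSums(present) == 1L), integer(1L))
  structure(list(season = season, species = species, regions = regions,
                 specific = specific, shared_all = shared_all,
                 total = sum(rowSums(present) > 0)),
            class = "shared_otu_summary")
}

#' @export
print.shared_otu_summary <- function(x, ...) {
  cat(sprintf("Shared OTUs (%s): %d present overall, %d shared by all\n",
              x$season, x$total, x$shared_all))
  print(x$specific)
  invisible(x)
}
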