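# Small in-code fixtures shared across test files.

# 2-sample, 3-OTU table with known aggregation arithmetic
tiny_table <- function() {
  m <- matrix(c(3L, 1L, 4L,
                2L, 0L, 6L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("OTU1", "OTU2", "OTU3")))
  otu_table(m)
}

# OTU1, OTU2 -> genus Rubus; OTU3 -> genus Smilax (species level)
tiny_taxonomy <- function() {
  taxon_assignments(list(
    OTU1 = list(c(family = "Rosaceae", genus = "Rubus",
                  species = "Rubus hirsutus")),
    OTU2 = list(c(family = "Rosaceae", genus = "Rubus",
                  species = "Rubus corchorifolius")),
    OTU3 = list(c(family = "Smilacaceae", genus = "Smilax",
                  species = "Smilax china"))),
    ranks = c("family", "genus", "species"))
}

tiny_metadata <- function() {
  sample_metadata(c("S1", "S2"),
                  c("sika_deer", "sika_deer"),
                  c("winter", "winter"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named proportions of a diet_profile, alphabetical order
profile_sorted <- function(p) {
  v <- stats::setNames(p$proportions, p$taxa)
  v[order(names(v))]
}

# random ranked lineage over synthetic names; prefix_pool controls how
# often candidates share high ranks
random_lineage <- function(depth_max = 5L, n_names = 3L) {
  depth <- sample.int(depth_max, 1L)
  vapply(seq_len(depth), function(d)
    paste0("r", d, "n", sample.int(n_names, 1L)), character(1L))
}

# random diet profile over a shared taxon universe
random_profile <- function(n_taxa = 8L, universe = letters) {
  k <- sample(2:n_taxa, 1L)
  taxa <- sample(universe, k)
  p <- stats::rgamma(k, 1)
  stats::setNames(p / sum(p), taxa)
}

# independent longest-common-prefix oracle for LCA collapsing
lcp_oracle <- function(cands) {
  if (length(cands) == 0L) return(NULL)
  ref <- cands[[1L]]
  out <- character(0)
  for (i in seq_along(ref)) {
    ok <- vapply(cands, function(x)
      length(x) >= i && x[[i]] == ref[[i]], logical(1L))
    if (all(ok)) out <- c(out, ref[[i]]) else break
  }
  if (length(out) == 0L) return(NULL)
  names(out) <- names(ref)[seq_along(out)]
  out
}

# hand-rank Kruskal-Wallis oracle (mid-ranks, tie correction)
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# naive UPGMA oracle returning the cophenetic distance matrix
upgma_cophenetic_oracle <- function(D) {
  n <- nrow(D)
  ids <- rownames(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  d <- D
  coph <- matrix(0, n, n, dimnames = list(ids, ids))
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(act)) for (b in seq_along(act)) {
      if (a >= b) next
      i <- act[a]; j <- act[b]
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      if (dij < bd) { bd <- dij; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    coph[clusters[[i]], clusters[[j]]] <- bd
    coph[clusters[[j]], clusters[[i]]] <- bd
    clusters[[length(clusters) + 1L]] <- c(clusters[[i]], clusters[[j]])
    active[c(i, j)] <- FALSE
    active[length(clusters)] <- TRUE
  }
  coph
}

# random symmetric distance matrix with zero diagonal
random_distance <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  D <- D + t(D)
  dimnames(D) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  D
}
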