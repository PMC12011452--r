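#' Collapse candidate lineages to their lowest common ancestor
#'
#' An OTU whose sequence matches two or more taxa is assigned to the lowest
#' taxonomic rank shared by all candidate lineages (e.g. two congeneric
#' species collapse to their genus). With a single candidate the lineage is
#' returned unchanged; with none the OTU is unassigned.
#'
#' @param candidates list of candidate lineages (named character vectors as
#'   produced by [read_taxonomy()]).
#' @return A named character vector (the consensus lineage, possibly
#'   truncated to a higher rank), or `NULL` when unassigned or when the
#'   candidates share no rank.
#' @export
lca_collapse <- function(candidates) {
  if (length(candidates) == 0L) return(NULL)
  if (length(candidates) == 1L) return(candidates[[1L]])
  depth <- min(lengths(candidates))
  keep <- 0L
  for (i in seq_len(depth)) {
    nm <- vapply(candidates, `[[`, character(1L), i)
    if (all(nm == nm[1L])) keep <- i else break
  }
  if (keep == 0L) return(NULL)
  candidates[[1L]][seq_len(keep)]
}

#' Resolve every OTU's taxonomy to a consensus lineage
#'
#' @param assignments a `taxon_assignments` object.
#' @return Named list (otu_id -> consensus lineage or `NULL`), with the
#'   rank vector carried over as attribute `ranks`.
#' @export
resolve_taxa <- function(assignments) {
  out <- lapply(assignments, lca_collapse)
  attr(out, "ranks") <- attr(assignments, "ranks")
  out
}

# Name of the diet category a resolved lineage contributes to at `rank`:
# the name at that rank when resolved that deep, otherwise the deepest
# available name (the OTU stays in the profile at a higher level).
taxon_at_rank <- function(lineage, rank) {
  if (is.null(lineage)) return(NA_character_)
  if (rank %in% names(lineage)) return(unname(lineage[[rank]]))
  unname(lineage[[length(lineage)]])
}

#' Convert OTU counts to per-sample relative read abundance (RRA)
#'
#' Counts of OTUs resolving to the same taxon at `rank` are summed per
#' sample and divided by the sample's retained read total, yielding one
#' proportion vector per sample (each summing to 1). OTUs resolved only to
#' a rank above `rank` contribute under their deepest resolved name;
#' unassigned OTUs are excluded when `drop_unassigned = TRUE` (the default,
#' matching the exclusion of unclassified sequences from diet composition)
#' and otherwise pooled into an `"unassigned"` category.
#'
#' @param table an [otu_table()].
#' @param resolved output of [resolve_taxa()] (or any named list
#'   otu_id -> lineage).
#' @param rank taxonomic rank of aggregation (must appear in the rank
#'   vector of `resolved`).
#' @param drop_unassigned drop reads from unassigned OTUs before
#'   normalizing?
#' @return An `rra_matrix`: samples x taxa proportion matrix with
#'   attributes `rank` and `lineages` (taxon -> its lineage prefix).
#' @export
to_rra <- function(table, resolved, rank = "genus", drop_unassigned = TRUE) {
  ranks <- attr(resolved, "ranks")
  if (!is.null(ranks) && !rank %in% ranks)
    stop("rank '", rank, "' not in the taxonomy rank vector")
  miss <- setdiff(colnames(table), names(resolved))
  if (length(miss) > 0L)
    stop("OTUs without a taxonomy entry: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  taxon <- vapply(colnames(table), function(o)
    taxon_at_rank(resolved[[o]], rank), character(1L))
  if (drop_unassigned) {
    keep <- !is.na(taxon)
    if (!any(keep)) stop("no assigned OTUs left after dropping unassigned")
    m <- table[, keep, drop = FALSE]
    taxon <- taxon[keep]
  } else {
    taxon[is.na(taxon)] <- "unassigned"
    m <- table
  }
  agg <- t(rowsum(t(unclass(m)), group = taxon))  # samples x taxa
  totals <- rowSums(agg)
  zero <- totals == 0
  if (any(zero))
    stop("sample(s) with zero retained reads: ",
         paste(utils::head(rownames(m)[zero], 5L), collapse = ", "))
  rra <- agg / totals
  lineages <- list()
  for (j in seq_along(taxon)) {
    tx <- taxon[j]
    if (is.null(lineages[[tx]]) && tx != "unassigned") {
      lin <- resolved[[colnames(m)[j]]]
      d <- if (rank %in% names(lin)) match(rank, names(lin)) else length(lin)
      lineages[[tx]] <- lin[seq_len(d)]
    }
  }
  structure(rra, rank = rank, lineages = lineages,
            class = c("rra_matrix", "matrix", "array"))
}

#' Construct a diet profile (one RRA vector for a species x season group)
#'
#' @param proportions named numeric vector of taxon proportions; must be in
#'   \[0,1\] and sum to 1 within 1e-9.
#' @param species,season group labels.
#' @param rank taxonomic rank of the categories.
#' @param n_samples number of fecal samples pooled into the profile.
#' @param lineages optional named list taxon -> lineage (for trait lookups).
#' @return Object of class `diet_profile`.
#' @export
diet_profile <- function(proportions, species = NA, season = NA,
                         rank = "genus", n_samples = NA_integer_,
                         lineages = NULL) {
  p <- proportions
  if (length(p) == 0L || is.null(names(p)))
    stop("diet profile needs a named, non-empty proportion vector")
  if (anyDuplicated(names(p))) stop("duplicate taxa in diet profile")
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  structure(list(species = species, season = season, rank = rank,
                 taxa = names(p), proportions = as.numeric(p),
                 n_samples = n_samples, lineages = lineages),
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("Diet profile [%s, %s] at %s rank: %d taxa, %s samples\n",
              x$species, x$season, x$rank, length(x$taxa),
              format(x$n_samples)))
  invisible(x)
}

# named proportion vector of a profile
profile_vector <- function(profile) {
  stats::setNames(profile$proportions, profile$taxa)
}

#' Pool per-sample RRA vectors into a group diet profile
#'
#' `mean_rra` (default) averages the per-sample proportion vectors with
#' equal weight, so a deeply sequenced sample cannot dominate the group
#' profile; `pooled_reads` sums the group's aggregated counts and
#' renormalizes, weighting samples by read depth.
#'
#' @param rra an `rra_matrix` from [to_rra()].
#' @param metadata `sample_metadata` covering the samples in `rra`.
#' @param species,season the group to pool.
#' @param method `"mean_rra"` or `"pooled_reads"`.
#' @param table,resolved the OTU table and resolved taxonomy; required for
#'   `method = "pooled_reads"`.
#' @param drop_unassigned passed through for `pooled_reads` recomputation.
#' @return A [diet_profile()] restricted to taxa with nonzero proportion.
#' @export
pool_group_profile <- function(rra, metadata, species, season,
                               method = c("mean_rra", "pooled_reads"),
                               table = NULL, resolved = NULL,
                               drop_unassigned = TRUE) {
  method <- match.arg(method)
  ids <- metadata$sample_id[metadata$species == species &
                              metadata$season == season]
  ids <- intersect(ids, rownames(rra))
  if (length(ids) == 0L)
    stop("no samples for group ", species, " / ", season)
  if (method == "mean_rra") {
    p <- colMeans(rra[ids, , drop = FALSE])
    p <- p / sum(p)
  } else {
    if (is.null(table) || is.null(resolved))
      stop("pooled_reads needs `table` and `resolved`")
    pooled <- t(as.matrix(colSums(table[ids, , drop = FALSE])))
    rownames(pooled) <- "pooled"
    pooled <- otu_table(pooled)
    p <- to_rra(pooled, resolved, rank = attr(rra, "rank"),
                drop_unassigned = drop_unassigned)[1L, ]
  }
  p <- p[p > 0]
  lin <- attr(rra, "lineages")
  diet_profile(p, species = species, season = season,
               rank = attr(rra, "rank"), n_samples = length(ids),
               lineages = if (!is.null(lin)) lin[names(p)] else NULL)
}

#' Top-n taxa of a diet profile with an "Others" remainder
#'
#' Taxa are ranked by descending proportion, ties broken alphabetically;
#' mass beyond the top `n` is reported as `Others` so the column still
#' sums to 1.
#'
#' @param profile a [diet_profile()].
#' @param n number of taxa to keep (>= 1).
#' @return data.frame with columns taxon, proportion.
#' @export
top_n_taxa <- function(profile, n = 10L) {
  if (n < 1L) stop("n must be >= 1")
  p <- profile_vector(profile)
  ord <- order(-p, names(p))
  p <- p[ord]
  top <- utils::head(p, n)
  rest <- sum(p) - sum(top)
  df <- data.frame(taxon = names(top), proportion = as.numeric(top),
                   stringsAsFactors = FALSE)
  if (length(p) > n)
    df <- rbind(df, data.frame(taxon = "Others", proportion = rest))
  rownames(df) <- NULL
  df
}

#' Growth-form composition of a diet profile
#'
#' Sums the profile's proportions by growth form (herb / shrub / arbor).
#' Lookup tries the taxon name itself, then climbs the taxon's lineage
#' from its own rank upward (species -> genus -> family ...); taxa that
#' never match are reported under `unknown`.
#'
#' @param profile a [diet_profile()] carrying lineage attributes.
#' @param map a [growth_form_map()].
#' @return Named numeric over herb, shrub, arbor, unknown; sums to 1.
#' @export
growth_form_percentages <- function(profile, map) {
  forms <- stats::setNames(map$growth_form, map$taxon)
  out <- c(herb = 0, shrub = 0, arbor = 0, unknown = 0)
  p <- profile_vector(profile)
  for (tx in names(p)) {
    path <- tx
    lin <- profile$lineages[[tx]]
    if (!is.null(lin)) path <- c(tx, rev(unname(lin)))
    hit <- forms[path]
    hit <- hit[!is.na(hit)]
    form <- if (length(hit) > 0L) hit[[1L]] else "unknown"
    out[form] <- out[form] + p[[tx]]
  }
  out / sum(out)
}
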