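#' Configuration for the synthetic metabarcoding dataset
#'
#' Emulates the study design the pipeline targets: 3 herbivore species x
#' 4 seasons x `samples_per_group` fecal samples, each sample an OTU read
#' vector drawn Dirichlet-multinomially around a known seasonal diet
#' profile. Every diet category is a genus from a common resource pool;
#' each genus is represented by 1-5 OTUs so the LCA/aggregation path is
#' exercised, and a fixed fraction of reads goes to lineage-less
#' (unassigned) OTUs.
#'
#' True group profiles are a dominant genus holding `dominant_mass` of the
#' diet plus a geometric tail (`tail_ratio`) over the remaining
#' `richness - 1` genera. Seasonal structure follows browse phenology:
#' summer pools are rich and relatively even, fall diets concentrate on
#' the dominant genus. The two ruminant-like consumers share their
#' dominant genus and most of their pool (high overlap); the hare-like
#' consumer feeds from the opposite end of the pool.
#'
#' @param samples_per_group fecal samples per species x season (default 30).
#' @param n_taxa size of the genus resource pool.
#' @param richness integer matrix (species x seasons) of true diet
#'   category counts S*.
#' @param dominant_mass numeric matrix (species x seasons) of the dominant
#'   genus' true diet share.
#' @param tail_ratio geometric decay of the non-dominant diet shares.
#' @param alpha Dirichlet concentration controlling inter-sample diet
#'   variation (larger = samples closer to the group profile).
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters.
#' @param unassigned_fraction expected fraction of reads on unassigned
#'   OTUs, in \[0, 1).
#' @param otus_per_taxon_max each genus is split over 1..this many OTUs.
#' @param muntjac_tail_rotation rotation of the second consumer's tail
#'   weights against the first's, de-aliasing their tail profiles.
#' @param seed RNG seed (required).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(samples_per_group = 30L,
                             n_taxa = 60L,
                             richness = NULL,
                             dominant_mass = NULL,
                             tail_ratio = 0.9,
                             alpha = 50,
                             depth_meanlog = log(2e4),
                             depth_sdlog = 0.4,
                             unassigned_fraction = 0.10,
                             otus_per_taxon_max = 5L,
                             muntjac_tail_rotation = 5L,
                             seed) {
  if (missing(seed)) stop("synthetic_config requires a seed")
  if (alpha <= 0) stop("alpha must be > 0")
  if (unassigned_fraction < 0 || unassigned_fraction >= 1)
    stop("unassigned_fraction must be in [0, 1)")
  if (samples_per_group < 1L) stop("samples_per_group must be >= 1")
  if (is.null(richness))
    richness <- matrix(c(35L, 45L, 20L, 30L,
                         33L, 42L, 18L, 28L,
                         38L, 40L, 36L, 35L),
                       nrow = 3L, byrow = TRUE,
                       dimnames = list(DIET_SPECIES, DIET_SEASONS))
  if (is.null(dominant_mass))
    dominant_mass <- matrix(c(0.50, 0.42, 0.68, 0.55,
                              0.52, 0.44, 0.68, 0.58,
                              0.48, 0.46, 0.50, 0.48),
                            nrow = 3L, byrow = TRUE,
                            dimnames = list(DIET_SPECIES, DIET_SEASONS))
  if (max(richness) > n_taxa) stop("richness exceeds the resource pool")
  structure(list(species = DIET_SPECIES, seasons = DIET_SEASONS,
                 samples_per_group = as.integer(samples_per_group),
                 n_taxa = as.integer(n_taxa), richness = richness,
                 dominant_mass = dominant_mass, tail_ratio = tail_ratio,
                 alpha = alpha, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog,
                 unassigned_fraction = unassigned_fraction,
                 otus_per_taxon_max = as.integer(otus_per_taxon_max),
                 muntjac_tail_rotation = as.integer(muntjac_tail_rotation),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# True genus-level profile for one species x season group. Deterministic in
# the config (no RNG), so the truth is identical across generator seeds.
# Species 1 and 2 use the low end of the pool with a shared dominant genus;
# species 3 uses the high end.
.true_profile <- function(config, sp_idx, season) {
  S <- config$richness[sp_idx, season]
  m <- config$dominant_mass[sp_idx, season]
  r <- config$tail_ratio
  pool <- config$n_taxa
  if (sp_idx < 3L) {
    dominant <- 1L
    tail_idx <- seq(2L, length.out = S - 1L)
    if (sp_idx == 2L) {
      rot <- config$muntjac_tail_rotation %% (S - 1L)
      tail_idx <- c(tail_idx[-seq_len(rot)], tail_idx[seq_len(rot)])
    }
  } else {
    dominant <- pool
    tail_idx <- seq(pool - 1L, by = -1L, length.out = S - 1L)
  }
  w <- r^(seq_len(S - 1L))
  p <- c(m, (1 - m) * w / sum(w))
  idx <- c(dominant, tail_idx)
  stats::setNames(p, .genus_name(idx))
}

.genus_name <- function(i) sprintf("Genus%02d", i)
.family_of <- function(i) sprintf("Family%02d", (i - 1L) %/% 5L + 1L)

#' Analytic niche truths implied by a synthetic configuration
#'
#' Applies the breadth and overlap definitions exactly to the true group
#' profiles: the oracle for recovery tests.
#'
#' @param truth a `synthetic_truth` object (or a `synthetic_config`).
#' @return list with `profiles` (named list of true proportion vectors),
#'   `breadth` (data.frame species, season, B, S, Ba) and `overlap`
#'   (per-season true Q matrices).
#' @export
true_metrics <- function(truth) {
  config <- if (inherits(truth, "synthetic_config")) truth else truth$config
  profiles <- list()
  breadth <- NULL
  overlap <- list()
  for (season in config$seasons) {
    vecs <- list()
    for (i in seq_along(config$species)) {
      sp <- config$species[i]
      p <- .true_profile(config, i, season)
      profiles[[paste(sp, season, sep = ".")]] <- p
      vecs[[sp]] <- p
      lb <- levins_breadth(p)
      breadth <- rbind(breadth,
                       data.frame(species = sp, season = season,
                                  B = lb$B, S = lb$S,
                                  Ba = standardized_breadth(lb$B, lb$S),
                                  stringsAsFactors = FALSE))
    }
    n <- length(vecs)
    Q <- diag(1, n)
    dimnames(Q) <- list(names(vecs), names(vecs))
    for (j in seq_len(n - 1L)) for (k in (j + 1L):n)
      Q[j, k] <- Q[k, j] <- pianka_overlap(vecs[[j]], vecs[[k]])
    overlap[[season]] <- Q
  }
  list(profiles = profiles, breadth = breadth, overlap = overlap)
}

#' Generate a synthetic OTU dataset with known niche truths
#'
#' Per sample: a diet is drawn from Dirichlet(alpha * P*), reads are drawn
#' multinomially at a lognormal depth, genus reads are split over that
#' genus' OTUs with fixed per-genus weights, and an `unassigned_fraction`
#' share of reads is routed to lineage-less OTUs. About 20% of assigned
#' OTUs carry two congeneric candidate species, so consensus collapsing is
#' required to reach the genus truth. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `table`
#'   ([otu_table()]), `metadata`, `taxonomy`, `growth_forms`, and `truth`
#'   (a `synthetic_truth`: config plus the output of [true_metrics()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  pool <- config$n_taxa
  genus <- .genus_name(seq_len(pool))
  family <- .family_of(seq_len(pool))

  # fixed OTU split per genus
  n_otus <- sample.int(config$otus_per_taxon_max, pool, replace = TRUE)
  otu_genus <- rep(seq_len(pool), n_otus)
  n_assigned <- length(otu_genus)
  otu_w <- unlist(lapply(n_otus, function(k) {
    g <- stats::rgamma(k, 1)
    g / sum(g)
  }))
  n_unassigned <- if (config$unassigned_fraction > 0) 15L else 0L
  otu_ids <- sprintf("OTU_%04d", seq_len(n_assigned + n_unassigned))
  ua_w <- if (n_unassigned > 0L) {
    g <- stats::rgamma(n_unassigned, 1)
    g / sum(g)
  } else numeric(0)

  # taxonomy: each assigned OTU is a species-level hit within its genus;
  # ~20% get a second congeneric candidate (consensus must fall to genus)
  two_cand <- stats::runif(n_assigned) < 0.2
  tax <- vector("list", n_assigned + n_unassigned)
  names(tax) <- otu_ids
  for (j in seq_len(n_assigned)) {
    g <- otu_genus[j]
    lin1 <- c(family = .family_of(g), genus = genus[g],
              species = paste(genus[g], sprintf("sp%d", j)))
    if (two_cand[j]) {
      lin2 <- lin1
      lin2["species"] <- paste(genus[g], sprintf("sp%db", j))
      tax[[j]] <- list(lin1, lin2)
    } else tax[[j]] <- list(lin1)
  }
  if (n_unassigned > 0L)
    for (j in seq_len(n_unassigned)) tax[[n_assigned + j]] <- list()
  taxonomy <- taxon_assignments(tax, ranks = c("family", "genus", "species"))

  # growth forms: one form per family; emitted at genus level for even
  # genus indices and at family level otherwise (exercises the fallback)
  forms <- c("herb", "shrub", "arbor")
  fam_ids <- unique(family)
  fam_form <- forms[(seq_along(fam_ids) - 1L) %% 3L + 1L]
  names(fam_form) <- fam_ids
  even <- seq_len(pool) %% 2L == 0L
  gf <- growth_form_map(
    c(genus[even], fam_ids),
    c(fam_form[family[even]], fam_form))

  truth_metrics <- true_metrics(config)
  groups <- expand.grid(species = config$species, seasons = config$seasons,
                        stringsAsFactors = FALSE)

  n_samples <- nrow(groups) * config$samples_per_group
  counts <- matrix(0L, n_samples, length(otu_ids),
                   dimnames = list(NULL, otu_ids))
  sample_id <- character(n_samples)
  meta_sp <- character(n_samples)
  meta_se <- character(n_samples)
  row <- 0L
  for (g in seq_len(nrow(groups))) {
    sp <- groups$species[g]
    se <- groups$seasons[g]
    sp_idx <- match(sp, config$species)
    p_true <- truth_metrics$profiles[[paste(sp, se, sep = ".")]]
    gidx <- match(names(p_true), genus)
    for (i in seq_len(config$samples_per_group)) {
      row <- row + 1L
      sample_id[row] <- sprintf("%s_%s_%02d", sp, substr(se, 1L, 2L), i)
      meta_sp[row] <- sp
      meta_se[row] <- se
      depth <- max(1000L, round(stats::rlnorm(1L, config$depth_meanlog,
                                              config$depth_sdlog)))
      diet <- stats::rgamma(length(p_true), shape = config$alpha * p_true)
      diet <- diet / sum(diet)
      n_ua <- if (n_unassigned > 0L)
        stats::rbinom(1L, depth, config$unassigned_fraction) else 0L
      g_reads <- stats::rmultinom(1L, depth - n_ua, diet)[, 1L]
      for (k in seq_along(gidx)) {
        if (g_reads[k] == 0L) next
        o <- which(otu_genus == gidx[k])
        if (length(o) == 1L) counts[row, o] <- g_reads[k]
        else counts[row, o] <-
            stats::rmultinom(1L, g_reads[k], otu_w[o])[, 1L]
      }
      if (n_ua > 0L)
        counts[row, n_assigned + seq_len(n_unassigned)] <-
          stats::rmultinom(1L, n_ua, ua_w)[, 1L]
    }
  }
  rownames(counts) <- sample_id
  keep <- colSums(counts) > 0L  # drop OTUs never observed
  table <- otu_table(counts[, keep, drop = FALSE])
  taxonomy <- taxon_assignments(taxonomy[colnames(table)],
                                ranks = attr(taxonomy, "ranks"))
  md <- sample_metadata(sample_id, meta_sp, meta_se)
  truth <- structure(c(truth_metrics, list(config = config,
                                           seed = config$seed)),
                     class = "synthetic_truth")
  structure(list(table = table, metadata = md, taxonomy = taxonomy,
                 growth_forms = gf, truth = truth),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to the pipeline's TSV dialects
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    otu_table = file.path(dir, "otu_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    growth_forms = file.path(dir, "growth_forms.tsv"))
  write_otu_table(dataset$table, paths["otu_table"])
  write_metadata(dataset$metadata, paths["metadata"])
  write_taxonomy(dataset$taxonomy, paths["taxonomy"])
  write_growth_forms(dataset$growth_forms, paths["growth_forms"])
  paths
}
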