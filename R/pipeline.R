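#' Run the diet-analysis workflow end to end
#'
#' Ties the stages together: alpha diversity (+ per-season Kruskal-Wallis
#' comparisons), rarefaction curves, consensus taxonomy collapsing and RRA
#' diet profiles (with top-n and growth-form tables), trophic niche
#' breadth/overlap, shared-OTU (Venn) summaries, Bray-Curtis NMDS
#' ordination with per-season intra/intergroup distances, and UPGMA
#' clustering. Any stage failure aborts with the stage name. With
#' `out_dir` set, all result tables are written as TSV (trees as Newick)
#' together with a run manifest.
#'
#' @param table an [otu_table()].
#' @param metadata `sample_metadata` covering the table's samples.
#' @param taxonomy `taxon_assignments` for the table's OTUs.
#' @param growth_forms optional [growth_form_map()].
#' @param rank aggregation rank for diet profiles and niche metrics.
#' @param pooling group pooling method, see [pool_group_profile()].
#' @param drop_unassigned exclude unassigned OTUs from diet composition?
#' @param overlap_threshold Pianka significance cutoff (strict >).
#' @param stages character subset of `"alpha"`, `"rarefaction"`,
#'   `"profiles"`, `"niche"`, `"venn"`, `"ordination"`, `"clustering"`.
#'   Stages `"niche"`, `"venn"`, `"ordination"` imply `"profiles"`.
#' @param top_n taxa kept in the per-group top tables.
#' @param rarefaction_samples sample ids to rarefy; default one sample per
#'   species x season group.
#' @param rarefaction_points depths per curve (spread to the sample total).
#' @param rarefaction_replicates subsamples per depth (median reported).
#' @param nmds_restarts,nmds_max_iter,nmds_tol NMDS solver settings.
#' @param seed master seed; each stochastic stage derives its own stream
#'   from it, so toggling stages does not change the others' results.
#' @param out_dir optional output directory for the result bundle.
#' @return Named list with one element per executed stage plus `manifest`.
#' @export
run_pipeline <- function(table, metadata, taxonomy, growth_forms = NULL,
                         rank = "genus",
                         pooling = c("mean_rra", "pooled_reads"),
                         drop_unassigned = TRUE, overlap_threshold = 0.6,
                         stages = c("alpha", "rarefaction", "profiles",
                                    "niche", "venn", "ordination",
                                    "clustering"),
                         top_n = 10L,
                         rarefaction_samples = NULL,
                         rarefaction_points = 8L,
                         rarefaction_replicates = 10L,
                         nmds_restarts = 20L, nmds_max_iter = 300L,
                         nmds_tol = 1e-6,
                         seed, out_dir = NULL) {
  pooling <- match.arg(pooling)
  stages <- match.arg(stages, several.ok = TRUE)
  if (missing(seed)) stop("run_pipeline requires a seed")
  if (any(c("niche", "venn", "ordination") %in% stages))
    stages <- union(stages, "profiles")
  md <- metadata[metadata$sample_id %in% rownames(table), , drop = FALSE]
  missing_md <- setdiff(rownames(table), md$sample_id)
  if (length(missing_md) > 0L)
    stop("pipeline input: samples without metadata: ",
         paste(utils::head(missing_md, 5L), collapse = ", "))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # one derived RNG stream per stochastic stage
  stage_seed <- function(offset) (seed + offset) %% .Machine$integer.max
  res <- list()
  seasons <- levels(droplevels(md$season))

  if ("alpha" %in% stages) res$alpha <- run_stage("alpha", {
    a <- alpha_diversity(table)
    tests <- do.call(rbind, lapply(seasons, function(se) {
      ids <- md$sample_id[md$season == se]
      sub <- a[a$sample_id %in% ids, ]
      if (length(unique(md$species[md$season == se])) < 2L) return(NULL)
      cbind(season = se, compare_alpha_diversity(sub, md, by = "species"))
    }))
    list(table = a, tests = tests)
  })

  if ("rarefaction" %in% stages)
    res$rarefaction <- run_stage("rarefaction", {
      ids <- rarefaction_samples
      if (is.null(ids)) {
        grp <- interaction(md$species, md$season, drop = TRUE)
        ids <- md$sample_id[!duplicated(grp)]
      }
      curves <- lapply(ids, function(s) {
        tot <- sum(table[s, ])
        depths <- unique(pmax(1L, round(seq(0.05, 1, length.out =
                                              rarefaction_points) * tot)))
        rarefaction_curve(table[s, ], depths,
                          n_replicates = rarefaction_replicates,
                          index = "shannon", seed = stage_seed(1L))
      })
      names(curves) <- ids
      curves
    })

  resolved <- NULL
  if ("profiles" %in% stages) res$profiles <- run_stage("profiles", {
    resolved <- resolve_taxa(taxonomy)  # assigns in the run_pipeline frame
    rra <- to_rra(table, resolved, rank = rank,
                  drop_unassigned = drop_unassigned)
    grp <- unique(md[, c("species", "season")])
    profiles <- lapply(seq_len(nrow(grp)), function(i)
      pool_group_profile(rra, md, grp$species[i], grp$season[i],
                         method = pooling, table = table,
                         resolved = resolved,
                         drop_unassigned = drop_unassigned))
    names(profiles) <- paste(grp$species, grp$season, sep = ".")
    top <- lapply(profiles, top_n_taxa, n = top_n)
    gf <- if (!is.null(growth_forms))
      lapply(profiles, growth_form_percentages, map = growth_forms)
    list(rra = rra, groups = profiles, top_taxa = top, growth_forms = gf)
  })

  if ("niche" %in% stages) res$niche <- run_stage("niche",
    niche_table(res$profiles$groups, threshold = overlap_threshold))

  if ("venn" %in% stages) res$venn <- run_stage("venn", {
    out <- lapply(seasons, function(se)
      shared_otu_counts(table, md, se, resolved = resolved))
    names(out) <- seasons
    out
  })

  if ("ordination" %in% stages) res$ordination <- run_stage("ordination", {
    # per-sample RRA at the OTU level (assigned OTUs)
    m <- unclass(table)
    if (drop_unassigned && !is.null(resolved)) {
      keep <- colnames(m)[!vapply(colnames(m), function(o)
        is.null(resolved[[o]]), logical(1L))]
      m <- m[, keep, drop = FALSE]
    }
    m <- m / rowSums(m)
    D <- bray_curtis_matrix(m)
    ord <- nmds(D, dims = 2L, n_restarts = nmds_restarts,
                max_iter = nmds_max_iter, tol = nmds_tol,
                seed = stage_seed(2L))
    dist_by_season <- lapply(seasons, function(se) {
      ids <- md$sample_id[md$season == se]
      sub <- D[ids, ids, drop = FALSE]
      intergroup_distances(distance_matrix(sub),
                           md$species[match(ids, md$sample_id)])
    })
    names(dist_by_season) <- seasons
    list(distances = D, nmds = ord, intergroup = dist_by_season)
  })

  if ("clustering" %in% stages) res$clustering <- run_stage("clustering", {
    D <- if (!is.null(res$ordination)) res$ordination$distances
    else bray_curtis_matrix(unclass(table) / rowSums(table))
    upgma(D)
  })

  res$manifest <- data.frame(
    key = c("package", "version", "seed", "rank", "pooling",
            "drop_unassigned", "overlap_threshold", "stages",
            "n_samples", "n_otus"),
    value = c("dietniche",
              as.character(utils::packageVersion("dietniche")),
              seed, rank, pooling, drop_unassigned, overlap_threshold,
              paste(stages, collapse = "+"), nrow(table), ncol(table)),
    stringsAsFactors = FALSE)

  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

# serialize the result bundle as TSV/Newick files
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$alpha)) {
    w(res$alpha$table, "alpha_diversity.tsv")
    if (!is.null(res$alpha$tests)) w(res$alpha$tests, "alpha_tests.tsv")
  }
  if (!is.null(res$rarefaction)) {
    df <- do.call(rbind, lapply(names(res$rarefaction), function(s)
      cbind(sample_id = s, as.data.frame(res$rarefaction[[s]]))))
    w(df, "rarefaction.tsv")
  }
  if (!is.null(res$profiles)) {
    df <- do.call(rbind, lapply(names(res$profiles$groups), function(g) {
      p <- res$profiles$groups[[g]]
      data.frame(species = p$species, season = p$season, rank = p$rank,
                 taxon = p$taxa, proportion = p$proportions)
    }))
    w(df, "diet_profiles.tsv")
    df <- do.call(rbind, lapply(names(res$profiles$top_taxa), function(g)
      cbind(group = g, res$profiles$top_taxa[[g]])))
    w(df, "top_taxa.tsv")
    if (!is.null(res$profiles$growth_forms)) {
      df <- do.call(rbind,
                    lapply(names(res$profiles$growth_forms), function(g) {
        p <- res$profiles$growth_forms[[g]]
        data.frame(group = g, growth_form = names(p),
                   proportion = as.numeric(p))
      }))
      w(df, "growth_forms.tsv")
    }
  }
  if (!is.null(res$niche)) {
    w(res$niche$breadth, "niche_breadth.tsv")
    df <- do.call(rbind, lapply(names(res$niche$overlap), function(se) {
      Q <- res$niche$overlap[[se]]$Q
      data.frame(season = se, species = rownames(Q), round(Q, 6))
    }))
    w(df, "niche_overlap.tsv")
  }
  if (!is.null(res$venn)) {
    df <- do.call(rbind, lapply(res$venn, function(v)
      data.frame(season = v$season,
                 region = names(v$regions), count = v$regions)))
    w(df, "venn_regions.tsv")
  }
  if (!is.null(res$ordination)) {
    ord <- res$ordination$nmds
    df <- data.frame(sample_id = ord$ids, ord$coordinates,
                     stress = ord$stress)
    w(df, "nmds_coordinates.tsv")
    df <- do.call(rbind, lapply(names(res$ordination$intergroup),
                                function(se)
      cbind(season = se, res$ordination$intergroup[[se]]$summary)))
    w(df, "intergroup_distances.tsv")
  }
  if (!is.null(res$clustering))
    write_newick(res$clustering, file.path(out_dir, "upgma_tree.nwk"))
  w(res$manifest, "manifest.tsv")
  invisible(out_dir)
}
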