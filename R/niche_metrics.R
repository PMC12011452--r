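#' Levins' trophic niche breadth
#'
#' `B = 1 / sum(P_i^2)`, where `P_i` is the proportion of food category i
#' in the consumer's diet and S the number of categories it uses. B runs
#' from 1 (complete specialist) to S (perfectly even generalist).
#'
#' @param profile a [diet_profile()] or a proportion vector summing to 1.
#' @return list with `B` (breadth) and `S` (number of categories with
#'   nonzero proportion).
#' @export
levins_breadth <- function(profile) {
  p <- if (inherits(profile, "diet_profile")) profile_vector(profile)
       else as.numeric(profile)
  if (length(p) == 0L) stop("empty diet profile")
  p <- check_proportions(p)
  p <- p[p > 0]
  if (length(p) == 0L) stop("diet profile has no positive proportion")
  list(B = 1 / sum(p^2), S = length(p))
}

#' Hurlbert's standardized niche breadth
#'
#' `Ba = (B - 1) / (S - 1)`, rescaling Levins' B to \[0, 1\]: 0 is the
#' minimum diet breadth (single food category dominates completely) and 1
#' the maximum (uniform use of all S categories). For S = 1 the breadth is
#' 0 by convention.
#'
#' @param B Levins' breadth, `1 <= B <= S`.
#' @param S number of food categories.
#' @return Ba in \[0, 1\].
#' @export
standardized_breadth <- function(B, S) {
  if (B < 1 - 1e-9 || B > S + 1e-9)
    stop("B must satisfy 1 <= B <= S (B = ", format(B), ", S = ", S, ")")
  if (S <= 1L) return(0)
  max(0, min(1, (B - 1) / (S - 1)))
}

#' Niche breadth summary of a diet profile
#'
#' @param profile a [diet_profile()].
#' @return Object of class `niche_result`: list with species, season,
#'   `B`, `S`, `Ba` and the profile's Shannon dietary diversity (nats).
#' @export
niche_breadth <- function(profile) {
  lb <- levins_breadth(profile)
  structure(list(species = profile$species, season = profile$season,
                 rank = profile$rank, B = lb$B, S = lb$S,
                 Ba = standardized_breadth(lb$B, lb$S),
                 dietary_diversity = shannon(profile_vector(profile))),
            class = "niche_result")
}

#' @export
print.niche_result <- function(x, ...) {
  cat(sprintf("Niche breadth [%s, %s]: B = %.2f, S = %d, Ba = %.3f, H' = %.2f\n",
              x$species, x$season, x$B, x$S, x$Ba, x$dietary_diversity))
  invisible(x)
}

#' Pianka's niche overlap index
#'
#' `Q_jk = sum(P_ij * P_ik) / sqrt(sum(P_ij^2) * sum(P_ik^2))`, the
#' cosine-type similarity of two consumers' resource-proportion vectors
#' aligned on the union of their food taxa (a taxon absent from one diet
#' contributes 0). Q ranges from 0 (no food item in common) to 1 (complete
#' overlap, i.e. proportional diets).
#'
#' @param profile_j,profile_k [diet_profile()] objects at the same rank,
#'   or plain named proportion vectors.
#' @return Q in \[0, 1\].
#' @export
pianka_overlap <- function(profile_j, profile_k) {
  pj <- if (inherits(profile_j, "diet_profile")) profile_vector(profile_j)
        else profile_j
  pk <- if (inherits(profile_k, "diet_profile")) profile_vector(profile_k)
        else profile_k
  if (inherits(profile_j, "diet_profile") &&
      inherits(profile_k, "diet_profile") &&
      !identical(profile_j$rank, profile_k$rank))
    stop("profiles aggregated at different ranks: ",
         profile_j$rank, " vs ", profile_k$rank)
  if (is.null(names(pj)) || is.null(names(pk)))
    stop("profiles must be named to align on the taxon union")
  taxa <- union(names(pj), names(pk))
  x <- stats::setNames(numeric(length(taxa)), taxa)
  y <- x
  x[names(pj)] <- pj
  y[names(pk)] <- pk
  if (sum(x) == 0 || sum(y) == 0) stop("zero-vector diet profile")
  q <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  min(1, max(0, q))
}

#' Pairwise niche overlap matrix for one season
#'
#' All pairwise Pianka indices among the supplied species profiles, with a
#' significance flag for overlaps strictly greater than the threshold
#' (Q > 0.6 is conventionally read as a significant overlap; exactly 0.6
#' is not flagged).
#'
#' @param profiles list of >= 2 [diet_profile()]s (one species each) at a
#'   common rank; names default to the profiles' species labels.
#' @param threshold significance cutoff (default 0.6, strict).
#' @return Object of class `overlap_matrix`: list with `season`, `Q`
#'   (symmetric, unit diagonal), `significant` (logical matrix) and
#'   `threshold`.
#' @export
overlap_matrix <- function(profiles, threshold = 0.6) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  ranks <- unique(vapply(profiles, `[[`, character(1L), "rank"))
  if (length(ranks) > 1L)
    stop("profiles aggregated at different ranks: ",
         paste(ranks, collapse = ", "))
  nm <- names(profiles)
  if (is.null(nm))
    nm <- vapply(profiles, function(p) as.character(p$species), character(1L))
  n <- length(profiles)
  Q <- diag(1, n)
  dimnames(Q) <- list(nm, nm)
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    Q[j, k] <- Q[k, j] <- pianka_overlap(profiles[[j]], profiles[[k]])
  }
  seasons <- unique(vapply(profiles, function(p) as.character(p$season),
                           character(1L)))
  structure(list(season = if (length(seasons) == 1L) seasons else NA,
                 species = nm, Q = Q,
                 significant = Q > threshold,
                 threshold = threshold),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Pianka overlap (%s), significance Q > %.2f\n",
              x$season, x$threshold))
  print(round(x$Q, 2))
  invisible(x)
}

#' Seasonal niche table (breadth, overlap, dietary diversity)
#'
#' The analysis' summary table: per species x season Levins' B, category
#' count S, Hurlbert's Ba and Shannon dietary diversity, plus one pairwise
#' overlap matrix per season.
#'
#' @param profiles list of [diet_profile()]s covering species x season
#'   groups.
#' @param threshold overlap significance cutoff.
#' @return list with `breadth` (data.frame) and `overlap` (named list of
#'   [overlap_matrix()] per season).
#' @export
niche_table <- function(profiles, threshold = 0.6) {
  br <- do.call(rbind, lapply(profiles, function(p) {
    nr <- niche_breadth(p)
    data.frame(species = as.character(nr$species),
               season = as.character(nr$season),
               B = nr$B, S = nr$S, Ba = nr$Ba,
               dietary_diversity = nr$dietary_diversity,
               stringsAsFactors = FALSE)
  }))
  rownames(br) <- NULL
  seasons <- unique(br$season)
  ov <- lapply(seasons, function(se) {
    ps <- profiles[vapply(profiles, function(p)
      as.character(p$season) == se, logical(1L))]
    names(ps) <- vapply(ps, function(p) as.character(p$species),
                        character(1L))
    if (length(ps) >= 2L) overlap_matrix(ps, threshold = threshold) else NULL
  })
  names(ov) <- seasons
  list(breadth = br, overlap = ov[!vapply(ov, is.null, logical(1L))])
}
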