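#' Hill-number alpha diversity
#'
#' Effective number of species of order \code{q}: for \code{q = 1},
#' \code{exp(-sum p_i log p_i)} (the exponential of Shannon entropy, natural
#' log — Hill numbers are base-invariant); otherwise
#' \code{(sum p_i^q)^(1/(1-q))}, evaluated over the strains with positive
#' abundance. The function is continuous at \code{q = 1}.
#'
#' @param x non-negative abundance vector.
#' @param q diversity order, >= 0.
#' @return effective number of species; \code{NA} for an all-zero community
#'   (an extinct community has no defined diversity).
#' @examples
#' hillDiversity(rep(3, 8))            # 8
#' hillDiversity(c(0.5, 0.25, 0.25))   # 2 * sqrt(2)
#' @export
hillDiversity <- function(x, q = 1) {
  stopifnot(is.numeric(x), all(x >= 0), length(q) == 1L, q >= 0)
  tot <- sum(x)
  if (tot == 0) return(NA_real_)
  p <- x[x > 0] / tot
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Convert ordinal scores to numeric abundances
#'
#' @param score character vector of scores (\code{gone}, \code{micro},
#'   \code{very_weak}, \code{weak}, \code{strong}).
#' @param map named numeric map, see \code{\link{scoreAbundanceMap}}.
#' @return numeric abundances.
#' @export
scoreToAbundance <- function(score, map = scoreAbundanceMap()) {
  if (any(diff(map[.SCORES]) <= 0) || map[["gone"]] != 0)
    stop("abundance map must be strictly increasing from gone = 0")
  bad <- setdiff(unique(score), names(map))
  if (length(bad)) stop("unknown score label(s): ", paste(bad, collapse = ", "))
  unname(map[score])
}

#' Community-by-strain abundance matrix for one week
#'
#' Pivots the long observation table into a wells x strains matrix for the
#' experimental (non-blank) wells of the requested week, with abundances
#' taken either from the ordinal score via the abundance map
#' (\code{source = "score"}, the default) or directly from colony counts
#' (\code{source = "count"}).
#'
#' @param obs long observation table (or a \code{MutualismExperiment}).
#' @param layout the layout (taken from the experiment if omitted).
#' @param week week to extract.
#' @param source \code{"score"} or \code{"count"}.
#' @param map abundance map used when \code{source = "score"}.
#' @return numeric matrix with rownames \code{plate:well}, one column per
#'   strain, plus attributes \code{community_type} and \code{treatment}
#'   (character vectors aligned with the rows).
#' @export
abundanceMatrix <- function(obs, layout = NULL, week = 7L,
                            source = c("score", "count"),
                            map = scoreAbundanceMap()) {
  source <- match.arg(source)
  if (is(obs, "MutualismExperiment")) {
    if (is.null(layout)) layout <- layoutOf(obs)
    obs <- observations(obs)
  }
  if (is.null(layout)) stop("a layout is required")
  o <- obs[obs$week == week, , drop = FALSE]
  if (!nrow(o)) stop("no observations for week ", week)
  w <- wells(layout)
  w <- w[w$treatment != "blank", , drop = FALSE]
  key <- paste(w$plate_id, w$well_id, sep = ":")
  o$key <- paste(o$plate_id, o$well_id, sep = ":")
  o <- o[o$key %in% key, , drop = FALSE]
  strains <- panelOf(layout)$strain_id
  val <- if (source == "score") scoreToAbundance(o$score, map)
         else as.numeric(o$colony_count)
  m <- matrix(0, length(key), length(strains),
              dimnames = list(key, strains))
  m[cbind(match(o$key, key), match(o$strain_id, strains))] <- val
  attr(m, "community_type") <- w$community_type
  attr(m, "treatment") <- w$treatment
  m
}

#' Bray-Curtis dissimilarity between two communities
#'
#' \code{sum(|x - y|) / sum(x + y)}, in [0, 1]. Note the index is
#' scale-dependent as defined only through the ratio: \code{BC(2x, 2y) =
#' BC(x, y)}, but \code{BC(2x, y) != BC(x, y)} in general.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in [0, 1]; \code{NA} if both communities are empty.
#' @examples
#' brayCurtis(c(6, 0, 2), c(2, 2, 0)) # 2/3
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  denom <- sum(x + y)
  if (denom == 0) return(NA_real_)
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' All pairwise abundance-based Bray-Curtis dissimilarities between the rows
#' of a community x strain matrix (computed with \code{vegan::vegdist}).
#' Collapsed communities (all-zero rows) are excluded, with a message, since
#' their dissimilarity to anything is undefined — mirroring the exclusion of
#' collapsed communities from beta-diversity analyses.
#'
#' @param m non-negative community x strain matrix with at least two usable
#'   rows.
#' @return a symmetric \code{matrix} of dissimilarities with zero diagonal;
#'   the excluded community labels are attached as attribute
#'   \code{"excluded"}.
#' @export
pairwiseBeta <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  tot <- rowSums(m)
  excluded <- rownames(m)[tot == 0]
  if (is.null(rownames(m))) excluded <- which(tot == 0)
  if (length(excluded))
    message("excluding ", length(excluded),
            " collapsed (all-zero) communit",
            if (length(excluded) == 1) "y" else "ies")
  m <- m[tot > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least two non-collapsed communities")
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  attr(d, "excluded") <- excluded
  d
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS (via \code{vegan::monoMDS} with random restarts
#' through \code{vegan::metaMDS}): configuration distances are fitted to
#' weak-monotone (isotonic, ties averaged) transforms of the input
#' dissimilarities by minimizing stress-1, and the lowest-stress solution
#' over the restarts is returned. Seeded and reproducible.
#'
#' @param d dissimilarity matrix or \code{dist}.
#' @param k embedding dimension (2 for ordination plots).
#' @param nRestarts random restarts.
#' @param seed integer seed.
#' @return an \code{\link{NMDSFit-class}} object.
#' @export
runNMDS <- function(d, k = 2L, nRestarts = 50L, seed = 1L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1L) stop("need at least k + 1 communities")
  rng <- localRNG(as.integer(seed))
  on.exit(rng$restore(), add = TRUE)
  degenerate <- stats::sd(d) < 1e-12
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, trymax = nRestarts, trace = 0,
                   autotransform = FALSE, wascores = FALSE,
                   smin = 1e-9, sfgrmin = 1e-9)))
  new("NMDSFit", coordinates = unname(as.matrix(fit$points)),
      stress = fit$stress, seed = as.integer(seed),
      n_restarts = as.integer(nRestarts),
      converged = !degenerate && isTRUE(fit$converged))
}

#' Sensitivity of diversity statistics to the score-abundance map
#'
#' Recomputes per-community Hill diversity and mean pairwise Bray-Curtis
#' dissimilarity under alternative score maps and reports the Spearman rank
#' correlation of each statistic with the default map's values — a direct
#' check that the ordinal-to-numeric choice does not drive the conclusions.
#'
#' @param obs long observation table or \code{MutualismExperiment}.
#' @param layout layout (taken from the experiment if omitted).
#' @param week week to analyse.
#' @param maps named list of alternative maps.
#' @param q Hill order.
#' @return data.frame with one row per alternative map: rank correlations of
#'   alpha diversity and of the per-pair beta diversities.
#' @export
scoreSensitivity <- function(obs, layout = NULL, week = 7L,
                             maps = list(
                               linear = scoreAbundanceMap(1, 2, 3, 4),
                               coarse = scoreAbundanceMap(1, 5, 25, 125)),
                             q = 1) {
  ref <- abundanceMatrix(obs, layout, week = week, map = scoreAbundanceMap())
  alphaRef <- apply(ref, 1L, hillDiversity, q = q)
  betaRef <- stats::as.dist(pairwiseBeta(ref[rowSums(ref) > 0, ,
                                             drop = FALSE]))
  out <- lapply(names(maps), function(nm) {
    m <- abundanceMatrix(obs, layout, week = week, map = maps[[nm]])
    alpha <- apply(m, 1L, hillDiversity, q = q)
    beta <- stats::as.dist(pairwiseBeta(m[rowSums(m) > 0, , drop = FALSE]))
    data.frame(map = nm,
               alpha_rank_cor = stats::cor(alphaRef, alpha,
                                           method = "spearman",
                                           use = "complete.obs"),
               beta_rank_cor = stats::cor(as.vector(betaRef),
                                          as.vector(beta),
                                          method = "spearman"))
  })
  do.call(rbind, out)
}
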