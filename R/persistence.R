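#' Strain-retention and collapse proportions over time
#'
#' For every (week, community type, treatment) group: the proportion of
#' communities retaining each possible number of strains (a strain is
#' retained when its score is not \code{gone}), and the collapse proportion
#' (communities retaining zero strains). Blank wells are excluded.
#'
#' @param obs long observation table or \code{MutualismExperiment}.
#' @param layout layout (taken from the experiment if omitted).
#' @param collapse \code{"total"} (all strains gone, the default) or
#'   \code{"functional"} (all adenine over-producers gone, after which an
#'   exploited community is doomed even though other strains may linger for
#'   a few more transfers).
#' @return list with \code{retained} (data.frame: week, community_type,
#'   treatment, k, proportion) and \code{collapse} (data.frame: week,
#'   community_type, treatment, collapse_proportion, n_communities).
#' @export
persistenceCurve <- function(obs, layout = NULL,
                             collapse = c("total", "functional")) {
  collapse <- match.arg(collapse)
  if (is(obs, "MutualismExperiment")) {
    if (is.null(layout)) layout <- layoutOf(obs)
    obs <- observations(obs)
  }
  if (is.null(layout)) stop("a layout is required")
  weeksSeen <- sort(unique(obs$week))
  gaps <- setdiff(seq(min(weeksSeen), max(weeksSeen)), weeksSeen)
  if (length(gaps))
    stop("missing week(s): ", paste(gaps, collapse = ", "))
  w <- wells(layout)
  w <- w[w$treatment != "blank", , drop = FALSE]
  key <- paste(w$plate_id, w$well_id)
  obs$key <- paste(obs$plate_id, obs$well_id)
  obs <- obs[obs$key %in% key, , drop = FALSE]
  idx <- match(obs$key, key)
  obs$community_type <- w$community_type[idx]
  obs$treatment <- w$treatment[idx]

  retained <- stats::aggregate(
    obs$score != "gone",
    by = list(week = obs$week, community_type = obs$community_type,
              treatment = obs$treatment, key = obs$key),
    FUN = sum)
  names(retained)[5L] <- "k"
  nStrains <- length(unique(obs$strain_id))
  grp <- interaction(retained$week, retained$community_type,
                     retained$treatment, drop = TRUE)
  out <- lapply(levels(grp), function(g) {
    sub <- retained[grp == g, , drop = FALSE]
    ks <- 0:nStrains
    data.frame(week = sub$week[1L], community_type = sub$community_type[1L],
               treatment = sub$treatment[1L], k = ks,
               proportion = as.vector(table(factor(sub$k, levels = ks))) /
                 nrow(sub))
  })
  ret <- do.call(rbind, out)
  if (collapse == "total") {
    coll <- ret[ret$k == 0L,
                c("week", "community_type", "treatment", "proportion")]
    names(coll)[4L] <- "collapse_proportion"
  } else {
    ade <- obs[grepl("^AdeOP", obs$strain_id), , drop = FALSE]
    if (!nrow(ade)) stop("no AdeOP strains for functional collapse")
    adeGone <- stats::aggregate(
      ade$score == "gone",
      by = list(week = ade$week, community_type = ade$community_type,
                treatment = ade$treatment, key = ade$key),
      FUN = all)
    coll <- stats::aggregate(
      adeGone$x, by = list(week = adeGone$week,
                           community_type = adeGone$community_type,
                           treatment = adeGone$treatment), FUN = mean)
    names(coll)[4L] <- "collapse_proportion"
  }
  nComm <- stats::aggregate(
    retained$k, by = list(week = retained$week,
                          community_type = retained$community_type,
                          treatment = retained$treatment), FUN = length)
  coll <- merge(coll, stats::setNames(nComm, c("week", "community_type",
                                               "treatment",
                                               "n_communities")))
  rownames(ret) <- rownames(coll) <- NULL
  list(retained = ret, collapse = coll)
}

#' Treatment effect on alpha diversity, by plate-stratified permutation
#'
#' Difference in mean alpha diversity between dispersal-allowed and isolated
#' communities, with a two-sided permutation p-value obtained by shuffling
#' treatment labels within plates. The within-plate stratification plays the
#' role of a plate random effect: treatment labels are only exchangeable
#' among wells that share a plate. If some plate carries a single treatment,
#' the function falls back to a global shuffle with a warning.
#'
#' @param alpha numeric vector of per-community alpha diversities (collapsed
#'   communities should be coded 0, not NA).
#' @param treatment character/factor, \code{"dispersal_allowed"} or
#'   \code{"isolated"} per community.
#' @param plate plate identifier per community.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with \code{difference} (dispersal minus isolated),
#'   \code{means}, \code{p_perm}, \code{n_perm}, \code{stratified}.
#' @export
alphaComparison <- function(alpha, treatment, plate, nPerm = 999L,
                            seed = 1L) {
  stopifnot(length(alpha) == length(treatment),
            length(alpha) == length(plate))
  keep <- !is.na(alpha)
  alpha <- alpha[keep]; treatment <- as.character(treatment)[keep]
  plate <- as.character(plate)[keep]
  lv <- c("dispersal_allowed", "isolated")
  if (!all(treatment %in% lv)) stop("unknown treatment label")
  if (length(unique(treatment)) < 2L)
    stop("both treatments must be present")
  stratified <- all(vapply(split(treatment, plate),
                           function(x) length(unique(x)) == 2L, TRUE))
  if (!stratified)
    warning("some plate has a single treatment; ",
            "falling back to a global label shuffle")
  obs <- mean(alpha[treatment == lv[1L]]) -
    mean(alpha[treatment == lv[2L]])
  rng <- localRNG(as.integer(seed))
  on.exit(rng$restore(), add = TRUE)
  strata <- if (stratified) split(seq_along(alpha), plate)
            else list(seq_along(alpha))
  isD <- treatment == lv[1L]
  hits <- 0L
  for (i in seq_len(nPerm)) {
    permD <- isD
    for (s in strata) permD[s] <- isD[s][sample.int(length(s))]
    d <- mean(alpha[permD]) - mean(alpha[!permD])
    if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  list(difference = obs,
       means = c(dispersal_allowed = mean(alpha[isD]),
                 isolated = mean(alpha[!isD])),
       p_perm = (hits + 1L) / (nPerm + 1L), n_perm = as.integer(nPerm),
       stratified = stratified)
}

#' Beta-diversity trend over time with pair-blocked permutation inference
#'
#' Least-squares slope of pairwise beta diversity against week. Because the
#' same community pair contributes one value per week, weeks are permuted
#' jointly \emph{within} each pair-ID block: the permutation null preserves
#' the pair dependence structure (the role a pair-ID random effect plays in
#' a mixed model) while breaking any time trend. The p-value is two-sided.
#'
#' @param beta numeric vector of pairwise beta diversities.
#' @param week numeric week of each value.
#' @param pair pair identifier of each value.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return a \code{\link{TrendResult-class}} object.
#' @export
betaTrend <- function(beta, week, pair, nPerm = 999L, seed = 1L) {
  stopifnot(length(beta) == length(week), length(beta) == length(pair))
  keep <- is.finite(beta)
  beta <- beta[keep]; week <- week[keep]; pair <- as.character(pair)[keep]
  if (length(unique(week)) < 2L) stop("need at least two distinct weeks")
  if (length(unique(pair)) < 2L) stop("need at least two pair blocks")
  slopeOf <- function(y) {
    wc <- week - mean(week)
    sum(wc * y) / sum(wc^2)
  }
  obs <- slopeOf(beta)
  intercept <- mean(beta) - obs * mean(week)
  rng <- localRNG(as.integer(seed))
  on.exit(rng$restore(), add = TRUE)
  blocks <- split(seq_along(beta), pair)
  hits <- 0L
  y <- beta
  for (i in seq_len(nPerm)) {
    for (bl in blocks) y[bl] <- beta[bl][sample.int(length(bl))]
    if (abs(slopeOf(y)) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  new("TrendResult", slope = obs, intercept = intercept,
      p_perm = (hits + 1L) / (nPerm + 1L),
      n_pairs = length(blocks), n_perm = as.integer(nPerm))
}

#' Per-week pairwise beta diversity in long format
#'
#' Convenience builder for \code{\link{betaTrend}}: computes the pairwise
#' Bray-Curtis dissimilarities of the selected communities for every week
#' and stacks them with a unique pair ID. Pairs involving a collapsed
#' community in a given week are dropped for that week.
#'
#' @param obs long observation table or \code{MutualismExperiment}.
#' @param layout layout (taken from the experiment if omitted).
#' @param weeks integer weeks to include.
#' @param communityType,treatment subset of communities to compare.
#' @param source,map passed to \code{\link{abundanceMatrix}}.
#' @return data.frame with columns \code{week}, \code{pair}, \code{beta}.
#' @export
betaByWeek <- function(obs, layout = NULL, weeks = 1:7,
                       communityType = "mutualist_only",
                       treatment = c("isolated", "dispersal_allowed"),
                       source = "score", map = scoreAbundanceMap()) {
  treatment <- match.arg(treatment)
  if (is(obs, "MutualismExperiment")) {
    if (is.null(layout)) layout <- layoutOf(obs)
    obs <- observations(obs)
  }
  out <- vector("list", length(weeks))
  for (i in seq_along(weeks)) {
    m <- abundanceMatrix(obs, layout, week = weeks[i], source = source,
                         map = map)
    sel <- attr(m, "community_type") == communityType &
      attr(m, "treatment") == treatment
    m <- m[sel, , drop = FALSE]
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) < 2L) next
    d <- stats::as.dist(vegan::vegdist(m, method = "bray"))
    labs <- labels(d)
    ij <- which(lower.tri(diag(length(labs))), arr.ind = TRUE)
    out[[i]] <- data.frame(
      week = weeks[i],
      pair = paste(labs[ij[, 2L]], labs[ij[, 1L]], sep = "|"),
      beta = as.vector(d), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no week had two usable communities")
  res
}
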