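#' Per-community alpha diversity at one week
#'
#' Hill diversity of every experimental community at the given week, joined
#' with its plate, community type and treatment. Collapsed communities are
#' coded as alpha 0 (an extinct community has zero effective species), so
#' group means remain defined.
#'
#' @param obs long observation table or \code{MutualismExperiment}.
#' @param layout layout (taken from the experiment if omitted).
#' @param week week to analyse (Week 7, the analysis endpoint, by default).
#' @param q Hill order.
#' @param source,map passed to \code{\link{abundanceMatrix}}.
#' @return data.frame: plate_id, well_id, community_type, treatment, alpha.
#' @export
alphaTable <- function(obs, layout = NULL, week = 7L, q = 1,
                       source = "score", map = scoreAbundanceMap()) {
  if (is(obs, "MutualismExperiment")) {
    if (is.null(layout)) layout <- layoutOf(obs)
    obs <- observations(obs)
  }
  m <- abundanceMatrix(obs, layout, week = week, source = source, map = map)
  alpha <- apply(m, 1L, hillDiversity, q = q)
  alpha[is.na(alpha)] <- 0
  key <- do.call(rbind, strsplit(rownames(m), ":", fixed = TRUE))
  data.frame(plate_id = key[, 1L], well_id = key[, 2L],
             community_type = attr(m, "community_type"),
             treatment = attr(m, "treatment"), alpha = unname(alpha),
             stringsAsFactors = FALSE)
}

#' Run the full analysis chain on one experiment
#'
#' Computes, from the weekly observation table of a simulated (or imported)
#' experiment: per-community Hill (q = 1) alpha diversity at the final
#' analysis week with the plate-stratified treatment permutation test per
#' community type; retention/collapse summaries; per-treatment
#' beta-diversity-over-time trends among the mutualist-only communities with
#' pair-blocked permutation p-values; the richness-null standardized effect
#' size of beta diversity per treatment at the final week; recovery
#' proportions of the dispersal events; and a 2D NMDS of the final-week
#' mutualist-only communities.
#'
#' @param exp a \code{\link{MutualismExperiment}} (or a long observation
#'   table, in which case \code{layout} is required and the recovery block
#'   is skipped).
#' @param layout layout when \code{exp} is a plain table.
#' @param finalWeek analysis endpoint (Week 7 by default: the last week
#'   before the final transfer round, matching the reported endpoint).
#' @param q Hill order.
#' @param nRand null-model randomizations.
#' @param nPerm permutations for the treatment/trend tests.
#' @param nmdsRestarts NMDS random restarts.
#' @param seed integer seed for all resampling.
#' @param map score-abundance map.
#' @return named list of results (see Details in the package vignette).
#' @export
analyzeExperiment <- function(exp, layout = NULL, finalWeek = 7L, q = 1,
                              nRand = 1000L, nPerm = 999L,
                              nmdsRestarts = 50L, seed = 1L,
                              map = scoreAbundanceMap()) {
  events <- NULL
  if (is(exp, "MutualismExperiment")) {
    layout <- layoutOf(exp)
    events <- dispersalEvents(exp)
    obs <- observations(exp)
  } else obs <- exp
  if (is.null(layout)) stop("a layout is required")
  weeks <- seq_len(finalWeek)

  alpha <- alphaTable(obs, layout, week = finalWeek, q = q, map = map)
  alphaTests <- lapply(split(alpha, alpha$community_type), function(a) {
    alphaComparison(a$alpha, a$treatment, a$plate_id, nPerm = nPerm,
                    seed = seed)
  })

  persistence <- persistenceCurve(obs, layout)

  trends <- list(); betaLong <- list()
  for (tr in c("isolated", "dispersal_allowed")) {
    bw <- betaByWeek(obs, layout, weeks = weeks, treatment = tr, map = map)
    betaLong[[tr]] <- bw
    trends[[tr]] <- betaTrend(bw$beta, bw$week, bw$pair, nPerm = nPerm,
                              seed = seed)
  }

  m <- abundanceMatrix(obs, layout, week = finalWeek, map = map)
  mut <- attr(m, "community_type") == "mutualist_only"
  trt <- attr(m, "treatment")
  ses <- list()
  for (tr in c("isolated", "dispersal_allowed")) {
    mm <- m[mut & trt == tr, , drop = FALSE]
    mm <- mm[rowSums(mm) > 0, , drop = FALSE]
    ses[[tr]] <- if (nrow(mm) >= 2L)
      sesBeta(mm, nRand = nRand, seed = seed) else NULL
  }
  sesTests <- lapply(ses, function(s)
    if (!is.null(s) && sum(is.finite(s@pairs$ses)) >= 2L)
      sesTest(s@pairs$ses) else NULL)

  recovery <- NULL
  if (!is.null(events) && nrow(events)) {
    type <- ifelse(grepl("^E", events$plate_id), "exploited",
                   "mutualist_only")
    recovery <- recoveryProportion(events$recovered, type, seed = seed)
  }

  mMut <- m[mut, , drop = FALSE]
  mMut <- mMut[rowSums(mMut) > 0, , drop = FALSE]
  nmds <- if (nrow(mMut) >= 3L)
    runNMDS(vegan::vegdist(mMut, method = "bray"), k = 2L,
            nRestarts = nmdsRestarts, seed = seed) else NULL

  list(alpha = alpha, alphaTests = alphaTests, persistence = persistence,
       betaByWeek = betaLong, betaTrends = trends, ses = ses,
       sesTests = sesTests, recovery = recovery, nmds = nmds,
       finalWeek = finalWeek)
}

#' Headline sign checks for one simulated experiment
#'
#' Extracts the three qualitative findings as signed quantities from a
#' directed-dispersal run:
#' \enumerate{
#'   \item collapse proportions of exploited communities at the end of the
#'     experiment, isolated vs. dispersal-allowed;
#'   \item mean Hill (q = 1) alpha diversity at the final week by treatment,
#'     within each community type;
#'   \item beta-diversity-over-time slopes among mutualist-only communities,
#'     isolated vs. dispersal-allowed.
#' }
#'
#' @param exp a \code{\link{MutualismExperiment}} run under the directed
#'   policy.
#' @param finalWeek endpoint for the alpha and beta-trend analyses (Week 7,
#'   the last week before the final transfer round).
#' @param collapseWeek week at which collapse is assessed; persistence is a
#'   property of the whole experiment, so this defaults to the last scored
#'   week.
#' @param nPerm permutations for the dispersal-allowed trend p-value.
#' @param seed integer seed.
#' @return list with elements \code{collapse} (named numeric),
#'   \code{alpha} (list per community type of named numeric means),
#'   \code{slopes} (named numeric), \code{dispersalSlopeP} (p-value of the
#'   dispersal-allowed trend).
#' @export
headlineSigns <- function(exp, finalWeek = 7L, collapseWeek = NULL,
                          nPerm = 199L, seed = 1L) {
  layout <- layoutOf(exp)
  obs <- observations(exp)
  if (is.null(collapseWeek)) collapseWeek <- max(obs$week)
  pc <- persistenceCurve(obs, layout)$collapse
  cw <- pc[pc$week == collapseWeek & pc$community_type == "exploited", ]
  collapse <- stats::setNames(cw$collapse_proportion, cw$treatment)

  alpha <- alphaTable(obs, layout, week = finalWeek)
  alphaMeans <- lapply(split(alpha, alpha$community_type), function(a)
    tapply(a$alpha, a$treatment, mean))

  slopes <- numeric(0); pDisp <- NA_real_
  for (tr in c("isolated", "dispersal_allowed")) {
    bw <- betaByWeek(obs, layout, weeks = seq_len(finalWeek),
                     treatment = tr)
    t <- betaTrend(bw$beta, bw$week, bw$pair, nPerm = nPerm, seed = seed)
    slopes[tr] <- t@slope
    if (tr == "dispersal_allowed") pDisp <- t@p_perm
  }
  list(collapse = collapse, alpha = alphaMeans, slopes = slopes,
       dispersalSlopeP = pDisp)
}
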