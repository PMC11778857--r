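#' @import methods
NULL

## Controlled vocabularies used across the package
.GUILDS    <- c("AdeOP", "LysOP", "Cheater")
.RESOURCES <- c("adenine", "lysine")
.SCORES    <- c("gone", "micro", "very_weak", "weak", "strong")
.TREATMENTS <- c("isolated", "dispersal_allowed", "blank")
.COMMUNITY_TYPES <- c("mutualist_only", "exploited")

#' Plate/well/treatment design of a meta-community experiment
#'
#' An S4 container for the experimental design: one row per well with its
#' plate, community type (mutualist-only or exploited) and treatment
#' (isolated, dispersal-allowed, or blank), plus the per-well inoculum in
#' OD600 units and the strain panel the design refers to.
#'
#' @slot wells data.frame with columns \code{plate_id}, \code{well_id},
#'   \code{community_type}, \code{treatment}.
#' @slot inocula data.frame with columns \code{plate_id}, \code{well_id},
#'   \code{strain_id}, \code{initial_od}; blank wells have no rows.
#' @slot panel data.frame of strain specifications (see
#'   \code{\link{strainPanel}}).
#' @slot seed integer seed used for the well-position shuffle.
#'
#' @seealso \code{\link{buildLayout}}
#' @export
setClass("PlateLayout",
  representation(wells = "data.frame", inocula = "data.frame",
                 panel = "data.frame", seed = "integer"))

setValidity("PlateLayout", function(object) {
  w <- object@wells
  msgs <- character(0)
  need <- c("plate_id", "well_id", "community_type", "treatment")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns", paste(need, collapse = ", ")))
  if (!all(w$treatment %in% .TREATMENTS))
    msgs <- c(msgs, "unknown treatment label")
  if (!all(w$community_type %in% .COMMUNITY_TYPES))
    msgs <- c(msgs, "unknown community_type label")
  if (anyDuplicated(paste(w$plate_id, w$well_id)))
    msgs <- c(msgs, "duplicated plate/well identifiers")
  for (p in unique(w$plate_id)) {
    if (length(unique(w$community_type[w$plate_id == p])) != 1L)
      msgs <- c(msgs, sprintf("plate %s mixes community types", p))
  }
  inoc <- object@inocula
  if (nrow(inoc)) {
    blanks <- w$well_id[w$treatment == "blank"]
    key <- paste(inoc$plate_id, inoc$well_id)
    bkey <- paste(w$plate_id, w$well_id)[w$treatment == "blank"]
    if (any(key %in% bkey))
      msgs <- c(msgs, "blank wells must have empty inoculum")
    tot <- tapply(inoc$initial_od, key, sum)
    if (any(abs(tot - 0.1) > 1e-12))
      msgs <- c(msgs, "non-blank inocula must sum to 0.1 OD")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Result of a simulated meta-community experiment
#'
#' Holds the long-format weekly observation table, the directed-dispersal
#' event log, the layout and parameters that produced them, and the master
#' seed, so a run can be regenerated bit-identically.
#'
#' @slot observations data.frame with columns \code{week}, \code{plate_id},
#'   \code{well_id}, \code{strain_id}, \code{colony_count}, \code{score}.
#' @slot events data.frame dispersal event log (may have zero rows): columns
#'   \code{week}, \code{plate_id}, \code{strain_id}, \code{sink_well},
#'   \code{source_well}, \code{inoculum_density}, \code{recovered}.
#' @slot skipped data.frame of sink/strain pairs for which no source existed.
#' @slot layout the \code{\link{PlateLayout}} simulated.
#' @slot params list of simulation parameters (see \code{\link{growthParams}}).
#' @slot policy character, \code{"none"} or \code{"directed"}.
#' @slot seed integer master seed.
#'
#' @seealso \code{\link{runExperiment}}
#' @export
setClass("MutualismExperiment",
  representation(observations = "data.frame", events = "data.frame",
                 skipped = "data.frame", layout = "PlateLayout",
                 params = "list", policy = "character", seed = "integer"))

setValidity("MutualismExperiment", function(object) {
  obs <- object@observations
  need <- c("week", "plate_id", "well_id", "strain_id", "colony_count", "score")
  if (!all(need %in% names(obs)))
    return(paste("observations must have columns", paste(need, collapse = ", ")))
  if (nrow(obs)) {
    if (any(obs$colony_count < 0)) return("negative colony_count")
    if (!all(obs$score %in% .SCORES)) return("unknown score label")
    if (any((obs$colony_count == 0) != (obs$score == "gone")))
      return("score 'gone' must coincide with colony_count 0")
  }
  TRUE
})

#' Standardized effect size of beta diversity against a null model
#'
#' @slot mean_obs mean observed pairwise Bray-Curtis dissimilarity.
#' @slot mean_null,sd_null mean and standard deviation of the mean pairwise
#'   dissimilarity across randomized community matrices.
#' @slot ses standardized effect size, (mean_obs - mean_null) / sd_null.
#' @slot n_rand number of randomizations.
#' @slot pairs data.frame of per-pair observed values, null moments and SES.
#' @slot seed integer seed.
#'
#' @seealso \code{\link{sesBeta}}
#' @export
setClass("SESResult",
  representation(mean_obs = "numeric", mean_null = "numeric",
                 sd_null = "numeric", ses = "numeric", n_rand = "integer",
                 pairs = "data.frame", seed = "integer"))

setValidity("SESResult", function(object) {
  if (object@n_rand < 1L) return("n_rand must be >= 1")
  if (is.finite(object@ses) && object@sd_null > 0) {
    expect <- (object@mean_obs - object@mean_null) / object@sd_null
    if (abs(object@ses - expect) > 1e-12)
      return("ses must equal (mean_obs - mean_null)/sd_null")
  }
  TRUE
})

#' Beta-diversity-over-time trend with blocked permutation inference
#'
#' @slot slope least-squares slope of pairwise beta diversity against week.
#' @slot intercept least-squares intercept.
#' @slot p_perm permutation p-value from week-label shuffles within pair-ID
#'   blocks.
#' @slot n_pairs,n_perm numbers of pair blocks and permutations.
#' @export
setClass("TrendResult",
  representation(slope = "numeric", intercept = "numeric", p_perm = "numeric",
                 n_pairs = "integer", n_perm = "integer"))

setValidity("TrendResult", function(object) {
  if (!is.na(object@p_perm) && (object@p_perm <= 0 || object@p_perm > 1))
    return("p_perm must lie in (0, 1]")
  TRUE
})

#' Nonmetric multidimensional scaling fit
#'
#' Thin container around a 2D NMDS solution: the configuration, the Kruskal
#' stress-1 of the best restart, and convergence bookkeeping.
#'
#' @slot coordinates n x k matrix of ordination coordinates.
#' @slot stress Kruskal stress-1 of the reported solution.
#' @slot seed,n_restarts integers.
#' @slot converged logical.
#' @export
setClass("NMDSFit",
  representation(coordinates = "matrix", stress = "numeric",
                 seed = "integer", n_restarts = "integer",
                 converged = "logical"))

## ---- accessors ------------------------------------------------------------

#' @describeIn PlateLayout-class data.frame of wells and treatments
#' @param x a \code{PlateLayout} or \code{MutualismExperiment}
#' @export
wells <- function(x) {
  if (is(x, "MutualismExperiment")) x <- x@layout
  x@wells
}

#' @describeIn PlateLayout-class data.frame of per-well inocula
#' @export
inocula <- function(x) {
  if (is(x, "MutualismExperiment")) x <- x@layout
  x@inocula
}

#' @describeIn PlateLayout-class strain panel data.frame
#' @export
panelOf <- function(x) {
  if (is(x, "MutualismExperiment")) x <- x@layout
  x@panel
}

#' @describeIn MutualismExperiment-class long-format weekly observation table
#' @param x a \code{MutualismExperiment}
#' @export
observations <- function(x) x@observations

#' @describeIn MutualismExperiment-class dispersal event log
#' @export
dispersalEvents <- function(x) x@events

#' @describeIn MutualismExperiment-class layout the experiment was run on
#' @export
layoutOf <- function(x) x@layout

setMethod("show", "PlateLayout", function(object) {
  w <- object@wells
  cat("PlateLayout:", length(unique(w$plate_id)), "plates,",
      nrow(w), "wells\n")
  tab <- table(w$community_type, w$treatment)
  print(tab)
  invisible(object)
})

setMethod("show", "MutualismExperiment", function(object) {
  obs <- object@observations
  cat("MutualismExperiment:", length(unique(obs$week)), "scored weeks,",
      length(unique(paste(obs$plate_id, obs$well_id))), "wells, policy =",
      object@policy, "\n")
  cat("  ", nrow(obs), "observation records,", nrow(object@events),
      "dispersal events (seed", object@seed, ")\n")
  invisible(object)
})

setMethod("show", "SESResult", function(object) {
  cat(sprintf(
    "SESResult: mean_obs = %.4f, mean_null = %.4f, sd_null = %.4f\n",
    object@mean_obs, object@mean_null, object@sd_null))
  cat(sprintf("  SES = %.4f over %d randomizations (%d pairs)\n",
              object@ses, object@n_rand, nrow(object@pairs)))
  invisible(object)
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf(
    "TrendResult: slope = %.4f per week (intercept %.4f), p_perm = %.4g\n",
    object@slope, object@intercept, object@p_perm))
  cat(sprintf("  %d pair blocks, %d permutations\n",
              object@n_pairs, object@n_perm))
  invisible(object)
})

setMethod("show", "NMDSFit", function(object) {
  cat(sprintf("NMDSFit: %d points in %d dimensions, stress = %.4g (%s)\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@stress,
              if (object@converged) "converged" else "not converged"))
  invisible(object)
})
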