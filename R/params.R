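#' Growth and protocol parameters for the batch-culture simulator
#'
#' Parameters of the minimal Monod consumer-resource batch model with
#' growth-coupled resource release, serial 1:10 transfer every 48 h, and
#' weekly scoring. Rates are per hour; resources are in arbitrary units with
#' yield fixed at one cell per unit, so the release coefficients are measured
#' in "partner cells supportable per new producer cell".
#'
#' @param muMax maximal specific growth rate (per hour) shared by all strains
#'   before the over-production cost is applied.
#' @param K half-saturation constant of the required resource (resource
#'   units).
#' @param Y yield, cells produced per resource unit consumed.
#' @param yCoupled resource units released per new producer cell
#'   (growth-coupled over-production; 0 for the cheater).
#' @param yDeath resource units released per producer cell dying of
#'   starvation (lysis returns the intracellular amino-acid pool to the
#'   medium, as in engineered over-producer co-cultures); this keeps the
#'   cross-feeding flux from vanishing abruptly in starving communities.
#' @param leak constitutive resource release per producer cell per hour;
#'   this is what lets an obligate loop start from resource-free fresh
#'   medium.
#' @param capacityOD shared carrying capacity of one well in OD600 units:
#'   growth of every strain is scaled by \code{1 - totalOD/capacityOD}
#'   (the glucose ceiling of the dextrose medium, which amino-acid exchange
#'   cannot lift).
#' @param starvationFraction starvation death applies when the required
#'   resource falls below \code{starvationFraction * K}.
#' @param sigmaEnv standard deviation (log scale) of the per-well, per-strain,
#'   per-batch lognormal jitter on growth rate; 0 switches environmental
#'   stochasticity off and leaves transfer thinning and plating as the only
#'   noise sources.
#' @param dt Euler integration step in hours; must divide
#'   \code{batchDuration}.
#' @param batchDuration batch length in hours (48 h between transfers).
#' @param dilution fraction of the culture carried into fresh medium at each
#'   transfer (200 ul into 1800 ul = 0.1).
#' @param transfersPerWeek batches per scored "week" under the 48-h cadence.
#' @param weeks number of scored weeks.
#' @param cellsPerOD cells per ml represented by 1.0 OD600. The default is a
#'   deliberately scaled-down demographic unit so that extinction boundaries
#'   and plate counts are resolvable at desk scale; only abundance ratios
#'   enter the downstream analyses.
#' @param wellVolumeMl culture volume per well in ml.
#'
#' @return named list of validated parameters.
#' @examples
#' p <- growthParams()
#' p$dilution
#' @export
growthParams <- function(muMax = 0.45, K = 1, Y = 1, yCoupled = 0.6,
                         yDeath = 8, leak = 0.16, capacityOD = 1,
                         starvationFraction = 0.01,
                         sigmaEnv = 0.5, dt = 0.1, batchDuration = 48,
                         dilution = 0.1, transfersPerWeek = 3L, weeks = 8L,
                         cellsPerOD = 2e5, wellVolumeMl = 2) {
  p <- list(muMax = muMax, K = K, Y = Y, yCoupled = yCoupled,
            yDeath = yDeath, leak = leak,
            capacityOD = capacityOD,
            starvationFraction = starvationFraction, sigmaEnv = sigmaEnv,
            dt = dt, batchDuration = batchDuration, dilution = dilution,
            transfersPerWeek = as.integer(transfersPerWeek),
            weeks = as.integer(weeks), cellsPerOD = cellsPerOD,
            wellVolumeMl = wellVolumeMl)
  num <- c("muMax", "K", "Y", "yCoupled", "yDeath", "leak", "capacityOD",
           "starvationFraction",
           "sigmaEnv", "dt", "batchDuration", "cellsPerOD", "wellVolumeMl")
  for (nm in num)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0 ||
        !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single non-negative number")
  if (p$muMax <= 0 || p$K <= 0 || p$Y <= 0 || p$dt <= 0 ||
      p$capacityOD <= 0)
    stop("muMax, K, Y, capacityOD and dt must be positive")
  if (p$dilution <= 0 || p$dilution >= 1)
    stop("dilution must lie in (0, 1)")
  nSteps <- p$batchDuration / p$dt
  if (abs(nSteps - round(nSteps)) > 1e-9)
    stop("dt must divide batchDuration")
  if (p$transfersPerWeek < 1L || p$weeks < 1L)
    stop("transfersPerWeek and weeks must be >= 1")
  p
}

#' Ordinal plate-scoring thresholds
#'
#' Weekly plating spots 10 ul of each culture on a selective plate; the
#' resulting colony count is binned into the ordinal density score used in
#' the experiment: \code{gone} (0 colonies), \code{micro}, \code{very_weak}
#' (< 20 colonies, the extinction-trajectory boundary that triggers
#' dispersal), \code{weak}, and \code{strong}.
#'
#' @param platingVolumeMl volume plated, ml (10 ul).
#' @param platingEfficiency fraction of plated cells that form a colony.
#' @param microMax largest colony count scored \code{micro}.
#' @param veryWeakMax largest colony count scored \code{very_weak}; the
#'   default 19 encodes the "< 20 colonies" boundary.
#' @param weakMax largest colony count scored \code{weak}; larger counts are
#'   \code{strong}.
#' @return named list of validated thresholds.
#' @export
scoreThresholds <- function(platingVolumeMl = 0.01, platingEfficiency = 1,
                            microMax = 5L, veryWeakMax = 19L,
                            weakMax = 49L) {
  th <- list(platingVolumeMl = platingVolumeMl,
             platingEfficiency = platingEfficiency,
             microMax = as.integer(microMax),
             veryWeakMax = as.integer(veryWeakMax),
             weakMax = as.integer(weakMax))
  if (th$platingVolumeMl <= 0) stop("platingVolumeMl must be positive")
  if (th$platingEfficiency <= 0 || th$platingEfficiency > 1)
    stop("platingEfficiency must lie in (0, 1]")
  if (!(0L < th$microMax && th$microMax < th$veryWeakMax &&
        th$veryWeakMax < th$weakMax))
    stop("need 0 < microMax < veryWeakMax < weakMax")
  th
}

#' Map an ordinal density score to a numeric abundance
#'
#' The weekly scores are ordinal; diversity statistics need numbers. The
#' default map is geometric (order-of-magnitude spacing), reflecting that
#' each score tier corresponds to roughly a tenfold density band on the
#' plate; any strictly increasing map with \code{gone = 0} is accepted, and
#' \code{\link{scoreSensitivity}} quantifies how little the downstream
#' statistics depend on the choice.
#'
#' @param micro,very_weak,weak,strong positive, strictly increasing numeric
#'   abundances for the four non-extinct tiers.
#' @return named numeric vector over all five score labels.
#' @examples
#' scoreAbundanceMap()
#' @export
scoreAbundanceMap <- function(micro = 1, very_weak = 10, weak = 100,
                              strong = 1000) {
  m <- c(gone = 0, micro = micro, very_weak = very_weak, weak = weak,
         strong = strong)
  if (any(diff(m) <= 0))
    stop("score abundance map must be strictly increasing from gone = 0")
  m
}

#' Default run configuration
#'
#' Bundles the design, growth, scoring, abundance-map, dispersal and analysis
#' settings into one serializable list, as consumed by
#' \code{\link{cliSimulate}} and \code{\link{cliAnalyze}}.
#'
#' @param seed master seed.
#' @return nested named list.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    design = list(platesPerType = 2L, wellsPerPlate = 48L,
                  blanksPerPlate = 6L),
    strains = list(cost = 0.18, deathRate = 0.03,
                   cheaterDeathRate = 0.005, K = 1, cheaterK = 0.4),
    growth = growthParams(),
    scoring = scoreThresholds(),
    abundanceMap = as.list(scoreAbundanceMap()),
    dispersal = list(policy = "directed", rescueExtinct = FALSE,
                     meanOverPresent = TRUE),
    analysis = list(nRand = 1000L, nPerm = 999L, nmdsRestarts = 50L,
                    finalWeek = 7L, abundanceSource = "score"),
    seed = as.integer(seed))
}
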