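#' Initial well state for a layout
#'
#' Builds the vectorized state of every well in a layout: a wells x strains
#' matrix of cell numbers (the inoculum ODs converted with
#' \code{cellsPerOD * wellVolumeMl}) and a wells x 2 matrix of resource pools
#' (adenine, lysine), both starting at zero because fresh medium contains
#' neither amino acid. Blank wells start, and absent contamination remain,
#' identically zero.
#'
#' @param layout a \code{\link{PlateLayout}}.
#' @param params growth parameters, see \code{\link{growthParams}}.
#' @return an object of class \code{WellState}: a list with elements
#'   \code{cells} (matrix, cells per well), \code{resources} (matrix, units
#'   per well), \code{plate_id}, \code{well_id}, \code{strains},
#'   \code{time_h}.
#' @export
newWellState <- function(layout, params = growthParams()) {
  w <- wells(layout)
  panel <- panelOf(layout)
  strains <- panel$strain_id
  D <- matrix(0, nrow(w), length(strains),
              dimnames = list(NULL, strains))
  inoc <- inocula(layout)
  key <- paste(w$plate_id, w$well_id)
  ridx <- match(paste(inoc$plate_id, inoc$well_id), key)
  cidx <- match(inoc$strain_id, strains)
  D[cbind(ridx, cidx)] <- inoc$initial_od * params$cellsPerOD *
    params$wellVolumeMl
  R <- matrix(0, nrow(w), 2, dimnames = list(NULL, c("adenine", "lysine")))
  structure(list(cells = D, resources = R, plate_id = w$plate_id,
                 well_id = w$well_id, strains = strains, time_h = 0),
            class = "WellState")
}

## Per-strain vectors the integrator needs, in panel order.
.panelVectors <- function(panel, params) {
  consIdx <- match(panel$consumes, c("adenine", "lysine"))
  prodIdx <- match(panel$produces, c("adenine", "lysine")) # NA for cheater
  list(consIdx = consIdx, prodIdx = prodIdx,
       mu = params$muMax * (1 - panel$cost),
       m = panel$starvation_death_rate,
       K = if (is.null(panel$K)) rep(params$K, nrow(panel)) else panel$K,
       producer = !is.na(prodIdx))
}

#' Integrate one 48-hour batch of growth
#'
#' Fixed-step Euler integration of the minimal Monod consumer-resource model:
#' each strain grows at \code{muMax * (1 - cost) * R/(K + R)} on its required
#' resource, consumes \code{1/Y} resource units per new cell, and (producers
#' only) releases \code{yCoupled} units per new cell, \code{yDeath} units
#' per cell lost to starvation death (lysis release), and a constitutive
#' \code{leak} per cell per hour. All strains additionally share the
#' logistic glucose ceiling \code{1 - totalOD/capacityOD}, which bounds the
#' biomass one batch can reach. While the required resource is below
#' \code{starvationFraction * K} the strain dies at its starvation death
#' rate. Growth in a step is rescaled whenever it would overdraw the resource
#' pool, so resources and densities stay non-negative by construction.
#'
#' With \code{sigmaEnv > 0} each (well, strain) receives an i.i.d. lognormal
#' growth-rate factor drawn once per batch — environmental stochasticity that
#' makes the near-equivalent strains drift apart between wells while keeping
#' them exchangeable within a guild.
#'
#' @param state a \code{WellState}.
#' @param panel strain panel matching \code{state$strains}.
#' @param params growth parameters.
#' @param hours duration to integrate; default the full batch.
#' @return the updated \code{WellState}.
#' @export
stepBatch <- function(state, panel, params = growthParams(),
                      hours = params$batchDuration) {
  stopifnot(inherits(state, "WellState"),
            identical(state$strains, panel$strain_id))
  validateStrainPanel(panel)
  D <- state$cells
  R <- state$resources
  W <- nrow(D); S <- ncol(D)
  pv <- .panelVectors(panel, params)
  dt <- params$dt
  nSteps <- round(hours / dt)

  muMat <- matrix(pv$mu, W, S, byrow = TRUE)
  if (params$sigmaEnv > 0) {
    s <- params$sigmaEnv
    muMat <- muMat * matrix(
      stats::rlnorm(W * S, meanlog = -s^2 / 2, sdlog = s), W, S)
  }
  mMat <- matrix(pv$m, W, S, byrow = TRUE)
  KMat <- matrix(pv$K, W, S, byrow = TRUE)
  starvMat <- params$starvationFraction * KMat
  yMat <- matrix(ifelse(pv$producer, params$yCoupled, 0), W, S, byrow = TRUE)
  consA <- pv$consIdx == 1L
  consL <- pv$consIdx == 2L
  prodA <- pv$producer & pv$prodIdx == 1L
  prodL <- pv$producer & pv$prodIdx == 2L
  leakDt <- params$leak * dt

  Kcap <- params$capacityOD * params$cellsPerOD * params$wellVolumeMl
  for (step in seq_len(nSteps)) {
    Rreq <- R[, pv$consIdx, drop = FALSE]
    capF <- pmax(0, 1 - rowSums(D) / Kcap)
    grow <- D * muMat * (Rreq / (KMat + Rreq)) * capF * dt
    ## cap growth of each resource's consumers at the available pool
    needA <- rowSums(grow[, consA, drop = FALSE]) / params$Y
    needL <- rowSums(grow[, consL, drop = FALSE]) / params$Y
    fA <- ifelse(needA > R[, 1L], R[, 1L] / pmax(needA, 1e-300), 1)
    fL <- ifelse(needL > R[, 2L], R[, 2L] / pmax(needL, 1e-300), 1)
    grow[, consA] <- grow[, consA, drop = FALSE] * fA
    grow[, consL] <- grow[, consL, drop = FALSE] * fL
    death <- D * mMat * dt * (Rreq < starvMat)
    prodVecA <- rowSums((yMat * grow)[, prodA, drop = FALSE]) +
      params$yDeath * rowSums(death[, prodA, drop = FALSE]) +
      leakDt * rowSums(D[, prodA, drop = FALSE])
    prodVecL <- rowSums((yMat * grow)[, prodL, drop = FALSE]) +
      params$yDeath * rowSums(death[, prodL, drop = FALSE]) +
      leakDt * rowSums(D[, prodL, drop = FALSE])
    D <- pmax(D + grow - death, 0)
    R[, 1L] <- pmax(R[, 1L] + prodVecA -
                      rowSums(grow[, consA, drop = FALSE]) / params$Y, 0)
    R[, 2L] <- pmax(R[, 2L] + prodVecL -
                      rowSums(grow[, consL, drop = FALSE]) / params$Y, 0)
  }
  state$cells <- D
  state$resources <- R
  state$time_h <- state$time_h + nSteps * dt
  state
}

#' Serial 1:10 transfer into fresh medium
#'
#' Transfers a \code{dilution} fraction of each culture into fresh medium.
#' In stochastic mode the number of cells of each strain carried over is a
#' Poisson draw with mean \code{dilution * cells} (demographic bottleneck:
#' extinction is absorbing because Poisson(0) = 0); in deterministic mode the
#' cell numbers are multiplied by \code{dilution} exactly. Either way the
#' resource pools are carried over at the same fraction, since the fresh
#' medium contains neither amino acid.
#'
#' @param state a \code{WellState}.
#' @param params growth parameters.
#' @param stochastic logical; Poisson thinning (default) or exact scaling.
#' @return the updated \code{WellState}.
#' @export
serialTransfer <- function(state, params = growthParams(),
                           stochastic = TRUE) {
  stopifnot(inherits(state, "WellState"))
  D <- state$cells
  if (stochastic) {
    D <- matrix(stats::rpois(length(D), params$dilution * D),
                nrow(D), ncol(D), dimnames = dimnames(D))
    storage.mode(D) <- "double"
  } else {
    D <- D * params$dilution
  }
  state$cells <- D
  state$resources <- state$resources * params$dilution
  state
}

#' Plate 10 ul of every well and score each strain
#'
#' Colony counts are Poisson with mean
#' \code{cells * platingVolumeMl / wellVolumeMl * platingEfficiency}
#' (deterministic mode rounds the expectation), then binned into the ordinal
#' score: \code{gone} (0), \code{micro}, \code{very_weak} (at most 19 by
#' default), \code{weak}, \code{strong}.
#'
#' @param state a \code{WellState}.
#' @param thresholds see \code{\link{scoreThresholds}}.
#' @param params growth parameters (for the well volume).
#' @param stochastic logical; Poisson counts (default) or rounded
#'   expectations.
#' @return data.frame with columns \code{plate_id}, \code{well_id},
#'   \code{strain_id}, \code{colony_count}, \code{score}.
#' @export
plateAndScore <- function(state, thresholds = scoreThresholds(),
                          params = growthParams(), stochastic = TRUE) {
  stopifnot(inherits(state, "WellState"))
  lambda <- state$cells * thresholds$platingVolumeMl / params$wellVolumeMl *
    thresholds$platingEfficiency
  counts <- if (stochastic) {
    stats::rpois(length(lambda), lambda)
  } else {
    round(as.vector(lambda))
  }
  W <- nrow(state$cells); S <- ncol(state$cells)
  data.frame(
    plate_id = rep(state$plate_id, S),
    well_id = rep(state$well_id, S),
    strain_id = rep(state$strains, each = W),
    colony_count = as.integer(counts),
    score = scoreCounts(counts, thresholds),
    stringsAsFactors = FALSE)
}

#' Bin colony counts into ordinal density scores
#'
#' @param counts integer colony counts.
#' @param thresholds see \code{\link{scoreThresholds}}.
#' @return character vector of scores.
#' @export
scoreCounts <- function(counts, thresholds = scoreThresholds()) {
  ifelse(counts == 0, "gone",
    ifelse(counts <= thresholds$microMax, "micro",
      ifelse(counts <= thresholds$veryWeakMax, "very_weak",
        ifelse(counts <= thresholds$weakMax, "weak", "strong"))))
}

#' Run the full serial-transfer experiment
#'
#' Simulates every well of a layout through \code{weeks} scored weeks of
#' 48-hour batches (three batches per week by default), with a Poisson
#' demographic bottleneck at each transfer and Poisson plating at each weekly
#' scoring. Under the \code{"directed"} policy the dispersal module is
#' invoked at every weekly scoring from Week 2 through the penultimate week:
#' sink strains (1 to 19 colonies in a dispersal-allowed well) receive, at
#' the start of the next batch and right after its transfer, an inoculum of
#' 10\% of the mean density of the strains present in the sink, drawn from a
#' same-plate dispersal-allowed well where the strain is strong; recovery is
#' assessed by plating the sink two days (one batch) later.
#'
#' The run is fully reproducible: the same layout, parameters and seed give
#' byte-identical outputs.
#'
#' @param layout a \code{\link{PlateLayout}}.
#' @param params growth parameters.
#' @param thresholds scoring thresholds.
#' @param policy \code{"directed"} or \code{"none"}.
#' @param seed integer master seed.
#' @param stochastic logical; FALSE makes transfers and plating
#'   deterministic (environmental jitter is controlled separately by
#'   \code{params$sigmaEnv}).
#' @param rescueExtinct logical; are strains at 0 colonies rescue-eligible?
#'   The default (FALSE) reintroduces strains only while they are "going
#'   extinct", not after.
#' @param meanOverPresent logical; compute the dispersal inoculum from the
#'   mean density of strains present in the sink (default) or of all panel
#'   strains.
#' @param dispersalWeeks integer weeks at whose scoring dispersal is
#'   triggered; default 2 through \code{weeks - 1}.
#' @return a \code{\link{MutualismExperiment}}.
#' @examples
#' lay <- buildLayout(platesPerType = 1L, wellsPerPlate = 8L,
#'                    blanksPerPlate = 0L, seed = 1)
#' exp <- runExperiment(lay, growthParams(weeks = 2L), seed = 1)
#' head(observations(exp))
#' @export
runExperiment <- function(layout, params = growthParams(),
                          thresholds = scoreThresholds(),
                          policy = c("directed", "none"), seed = 1L,
                          stochastic = TRUE, rescueExtinct = FALSE,
                          meanOverPresent = TRUE, dispersalWeeks = NULL) {
  policy <- match.arg(policy)
  panel <- panelOf(layout)
  if (is.null(dispersalWeeks))
    dispersalWeeks <- if (params$weeks >= 3L) 2:(params$weeks - 1L)
                      else integer(0)
  rng <- localRNG(as.integer(seed))
  on.exit(rng$restore(), add = TRUE)

  state <- newWellState(layout, params)
  wellKey <- paste(state$plate_id, state$well_id)
  obsList <- vector("list", params$weeks)
  events <- list()
  skipped <- list()
  pending <- NULL   # events waiting to be applied at the next transfer

  for (week in seq_len(params$weeks)) {
    justApplied <- NULL
    for (b in seq_len(params$transfersPerWeek)) {
      if (!(week == 1L && b == 1L))
        state <- serialTransfer(state, params, stochastic)
      if (b == 1L && !is.null(pending) && nrow(pending)) {
        ap <- .applyPendingDispersal(state, pending, wellKey,
                                     meanOverPresent,
                                     params$wellVolumeMl)
        state <- ap$state
        justApplied <- ap$events
        skipped <- c(skipped, list(ap$skipped))
        pending <- NULL
      }
      state <- stepBatch(state, panel, params)
      if (b == 1L && !is.null(justApplied) && nrow(justApplied)) {
        ## recovery check: plate the sinks two days after reintroduction
        fu <- plateAndScore(state, thresholds, params, stochastic)
        fuKey <- paste(fu$plate_id, fu$well_id, fu$strain_id)
        evKey <- paste(justApplied$plate_id, justApplied$sink_well,
                       justApplied$strain_id)
        justApplied$recovered <-
          fu$score[match(evKey, fuKey)] == "strong"
        events <- c(events, list(justApplied))
        justApplied <- NULL
      }
    }
    obs <- plateAndScore(state, thresholds, params, stochastic)
    obs <- cbind(week = week, obs)
    obsList[[week]] <- obs
    if (policy == "directed" && week %in% dispersalWeeks) {
      sinks <- findSinks(obs, layout, thresholds, rescueExtinct)
      if (nrow(sinks)) {
        pending <- .matchSources(sinks, obs, layout, thresholds)
        pending$week <- week
      }
    }
  }

  events <- if (length(events)) do.call(rbind, events) else .emptyEvents()
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    .emptyEvents()[0, c("week", "plate_id", "strain_id", "sink_well")]
  new("MutualismExperiment",
      observations = do.call(rbind, obsList), events = events,
      skipped = skipped, layout = layout,
      params = c(params, list(thresholds = thresholds)),
      policy = policy, seed = as.integer(seed))
}

.emptyEvents <- function() {
  data.frame(week = integer(0), plate_id = character(0),
             strain_id = character(0), sink_well = character(0),
             source_well = character(0), inoculum_density = numeric(0),
             recovered = logical(0), stringsAsFactors = FALSE)
}

## Choose a source for every sink; returns the pending event table
.matchSources <- function(sinks, scores, layout, thresholds) {
  out <- vector("list", nrow(sinks))
  for (i in seq_len(nrow(sinks))) {
    src <- findSource(sinks$strain_id[i], sinks$well_id[i],
                      sinks$plate_id[i], scores, layout)
    out[[i]] <- data.frame(
      week = NA_integer_, plate_id = sinks$plate_id[i],
      strain_id = sinks$strain_id[i], sink_well = sinks$well_id[i],
      source_well = if (is.null(src)) NA_character_ else src,
      inoculum_density = NA_real_, recovered = NA,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Apply pending events to the post-transfer state; events without a source
## (or with an all-extinct sink) are moved to the skipped log.
.applyPendingDispersal <- function(state, pending, wellKey,
                                   meanOverPresent, wellVolumeMl = 2) {
  ok <- !is.na(pending$source_well)
  applied <- pending[ok, , drop = FALSE]
  skip <- pending[!ok, c("week", "plate_id", "strain_id", "sink_well"),
                  drop = FALSE]
  keep <- logical(nrow(applied))
  if (nrow(applied)) {
    for (i in seq_len(nrow(applied))) {
      row <- match(paste(applied$plate_id[i], applied$sink_well[i]), wellKey)
      dens <- state$cells[row, ]
      res <- applyDispersal(dens, applied$strain_id[i],
                            meanOverPresent = meanOverPresent)
      if (is.null(res)) next
      state$cells[row, ] <- res$densities
      applied$inoculum_density[i] <- res$inoculum / wellVolumeMl
      keep[i] <- TRUE
    }
  }
  skippedExtra <- applied[!keep, c("week", "plate_id", "strain_id",
                                   "sink_well"), drop = FALSE]
  list(state = state, events = applied[keep, , drop = FALSE],
       skipped = rbind(skip, skippedExtra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
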