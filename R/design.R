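#' Strain panel for an obligate adenine/lysine cross-feeding community
#'
#' Builds the table of strain specifications used throughout the package:
#' four adenine over-producers (AdeOP, consume lysine, release adenine), four
#' lysine over-producers (LysOP, consume adenine, release lysine) and,
#' optionally, one lysine cheater that consumes lysine but releases nothing
#' and bears no over-production cost. Strains within a guild are parameterized
#' identically ("near-equivalent species"): differences in fate between them
#' arise only from stochasticity in the simulator.
#'
#' @param cost dimensionless growth-rate penalty of over-production, applied
#'   to both mutualist guilds; the cheater always has cost 0.
#' @param deathRate per-hour death rate of mutualists while their required
#'   resource is below the starvation threshold.
#' @param cheaterDeathRate per-hour starvation death rate of the cheater;
#'   must not exceed \code{deathRate} (the cheater survives lysine starvation
#'   better than the mutualists).
#' @param K half-saturation constant (resource units) of the mutualists for
#'   their required amino acid.
#' @param cheaterK half-saturation constant of the cheater for lysine; must
#'   not exceed \code{K}. The lower default gives the cheater a scavenging
#'   advantage when lysine is scarce — the second face of its superior
#'   starvation performance — so exploitation excludes adenine
#'   over-producers strain by strain instead of starving whole wells at
#'   once.
#' @param cheater logical; include the cheater strain?
#'
#' @return data.frame with columns \code{strain_id}, \code{guild},
#'   \code{produces}, \code{consumes}, \code{cost},
#'   \code{starvation_death_rate}.
#' @examples
#' strainPanel()
#' @export
strainPanel <- function(cost = 0.18, deathRate = 0.03,
                        cheaterDeathRate = 0.005, K = 1, cheaterK = 0.4,
                        cheater = TRUE) {
  stopifnot(cost >= 0, cost < 1, deathRate >= 0, cheaterDeathRate >= 0,
            K > 0, cheaterK > 0)
  if (cheater && cheaterDeathRate > deathRate)
    stop("cheater starvation death rate must not exceed the mutualists'")
  if (cheater && cheaterK > K)
    stop("cheater half-saturation must not exceed the mutualists'")
  p <- data.frame(
    strain_id = c(paste0("AdeOP", 1:4), paste0("LysOP", 1:4)),
    guild = rep(c("AdeOP", "LysOP"), each = 4),
    produces = rep(c("adenine", "lysine"), each = 4),
    consumes = rep(c("lysine", "adenine"), each = 4),
    cost = cost,
    starvation_death_rate = deathRate,
    K = K,
    stringsAsFactors = FALSE)
  if (cheater) {
    p <- rbind(p, data.frame(
      strain_id = "Cheater", guild = "Cheater", produces = "none",
      consumes = "lysine", cost = 0,
      starvation_death_rate = cheaterDeathRate, K = cheaterK))
  }
  validateStrainPanel(p)
  p
}

## guild/production/consumption consistency rules
validateStrainPanel <- function(panel) {
  need <- c("strain_id", "guild", "produces", "consumes", "cost",
            "starvation_death_rate")
  if (!all(need %in% names(panel)))
    stop("strain panel must have columns ", paste(need, collapse = ", "))
  ok <- with(panel,
    (guild == "AdeOP"   & produces == "adenine" & consumes == "lysine") |
    (guild == "LysOP"   & produces == "lysine"  & consumes == "adenine") |
    (guild == "Cheater" & produces == "none"    & consumes == "lysine" &
       cost == 0))
  if (!all(ok))
    stop("invalid strain specification for: ",
         paste(panel$strain_id[!ok], collapse = ", "))
  if (any(panel$cost < 0 | panel$cost >= 1))
    stop("cost must lie in [0, 1)")
  if (any(panel$starvation_death_rate < 0))
    stop("starvation_death_rate must be >= 0")
  if (!is.null(panel$K) && any(panel$K <= 0))
    stop("K must be positive")
  invisible(TRUE)
}

#' Assemble the starting inoculum of one community
#'
#' Mutualist-only communities receive 0.0125 OD600 of each of the eight
#' mutualist strains (AdeOP:LysOP = 1:1); exploited communities receive
#' 0.01 OD600 of each mutualist plus 0.02 OD600 of the cheater
#' (AdeOP:LysOP:Cheater = 2:2:1). Either way the total is 0.1 OD600.
#'
#' @param communityType \code{"mutualist_only"} or \code{"exploited"}.
#' @param panel strain panel (see \code{\link{strainPanel}}).
#' @return named numeric vector of initial OD600 per strain.
#' @examples
#' sum(assembleInoculum("exploited", strainPanel())) # 0.1
#' @export
assembleInoculum <- function(communityType = c("mutualist_only", "exploited"),
                             panel = strainPanel()) {
  communityType <- match.arg(communityType)
  validateStrainPanel(panel)
  nAde <- sum(panel$guild == "AdeOP")
  nLys <- sum(panel$guild == "LysOP")
  nChe <- sum(panel$guild == "Cheater")
  if (nAde != 4L || nLys != 4L)
    stop("panel must contain exactly 4 AdeOP and 4 LysOP strains")
  if (communityType == "mutualist_only") {
    ids <- panel$strain_id[panel$guild != "Cheater"]
    inoc <- stats::setNames(rep(0.0125, length(ids)), ids)
  } else {
    if (nChe != 1L)
      stop("exploited communities require exactly one cheater in the panel")
    inoc <- stats::setNames(
      ifelse(panel$guild == "Cheater", 0.02, 0.01), panel$strain_id)
  }
  stopifnot(abs(sum(inoc) - 0.1) < 1e-12)
  inoc
}

#' Construct the plate/well/treatment layout
#'
#' Builds the full experimental design: \code{platesPerType} plates per
#' community type, each with \code{wellsPerPlate} wells of which
#' \code{blanksPerPlate} are blanks (contamination monitors) and the rest are
#' split as evenly as possible between isolated and dispersal-allowed
#' communities. Which physical well position gets which role is decided by a
#' seeded uniform shuffle, so the same seed always yields the same layout.
#'
#' The defaults reproduce the reference design: 2 plates per type, 48 wells,
#' 6 blanks, hence 21 isolated + 21 dispersal-allowed communities per plate
#' and 168 experimental communities in total (84 per community type).
#'
#' @param platesPerType plates per community type (>= 1).
#' @param wellsPerPlate wells on each plate.
#' @param blanksPerPlate blank wells on each plate.
#' @param panel strain panel.
#' @param seed integer seed for the well-position shuffle.
#' @return a \code{\link{PlateLayout}}.
#' @examples
#' lay <- buildLayout(seed = 1)
#' table(wells(lay)$treatment)
#' @export
buildLayout <- function(platesPerType = 2L, wellsPerPlate = 48L,
                        blanksPerPlate = 6L, panel = strainPanel(),
                        seed = 1L) {
  platesPerType <- as.integer(platesPerType)
  wellsPerPlate <- as.integer(wellsPerPlate)
  blanksPerPlate <- as.integer(blanksPerPlate)
  if (platesPerType < 1L) stop("platesPerType must be >= 1")
  if (wellsPerPlate < blanksPerPlate + 2L)
    stop("wellsPerPlate must be at least blanksPerPlate + 2")
  nExp <- wellsPerPlate - blanksPerPlate
  nIso <- nExp %/% 2L
  nDisp <- nExp - nIso

  rng <- localRNG(as.integer(seed))
  on.exit(rng$restore(), add = TRUE)

  plateIds <- c(paste0("M", seq_len(platesPerType)),
                paste0("E", seq_len(platesPerType)))
  types <- rep(c("mutualist_only", "exploited"), each = platesPerType)
  wellIds <- sprintf("W%02d", seq_len(wellsPerPlate))

  wl <- list(); il <- list()
  for (i in seq_along(plateIds)) {
    roles <- c(rep("blank", blanksPerPlate), rep("isolated", nIso),
               rep("dispersal_allowed", nDisp))
    roles <- roles[sample.int(wellsPerPlate)]
    wl[[i]] <- data.frame(plate_id = plateIds[i], well_id = wellIds,
                          community_type = types[i], treatment = roles,
                          stringsAsFactors = FALSE)
    inoc <- assembleInoculum(types[i], panel)
    keep <- wellIds[roles != "blank"]
    il[[i]] <- data.frame(
      plate_id = plateIds[i],
      well_id = rep(keep, each = length(inoc)),
      strain_id = rep(names(inoc), length(keep)),
      initial_od = rep(unname(inoc), length(keep)),
      stringsAsFactors = FALSE)
  }
  new("PlateLayout", wells = do.call(rbind, wl),
      inocula = do.call(rbind, il), panel = panel, seed = as.integer(seed))
}

## Run code under a temporary RNG state seeded with `seed`; restores the
## caller's RNG so seeded helpers do not perturb the global stream.
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
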