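# Shared fixtures: everything is built in code at test time.

# Small full design: 1 plate per type, 8 wells, no blanks (fast to simulate).
smallLayout <- function(seed = 1L, wells = 8L, panel = strainPanel()) {
  buildLayout(platesPerType = 1L, wellsPerPlate = wells,
              blanksPerPlate = 0L, panel = panel, seed = seed)
}

# Fast growth parameters for short runs.
fastParams <- function(weeks = 3L, ...) {
  growthParams(weeks = weeks, ...)
}

# A toy long-format observation table built from a wells x strains count
# matrix for a single week.
toyObs <- function(counts, week = 1L, plate = "M1",
                   thresholds = scoreThresholds()) {
  stopifnot(is.matrix(counts))
  wellIds <- sprintf("W%02d", seq_len(nrow(counts)))
  strains <- colnames(counts)
  data.frame(
    week = week,
    plate_id = plate,
    well_id = rep(wellIds, ncol(counts)),
    strain_id = rep(strains, each = nrow(counts)),
    colony_count = as.integer(counts),
    score = scoreCounts(as.integer(counts), thresholds),
    stringsAsFactors = FALSE)
}

# A matching layout for toyObs matrices (single plate, all isolated).
toyLayout <- function(counts, plate = "M1",
                      communityType = "mutualist_only",
                      treatment = "isolated", panel = strainPanel()) {
  wellIds <- sprintf("W%02d", seq_len(nrow(counts)))
  w <- data.frame(plate_id = plate, well_id = wellIds,
                  community_type = communityType, treatment = treatment,
                  stringsAsFactors = FALSE)
  inoc <- assembleInoculum(communityType, panel)
  il <- data.frame(plate_id = plate,
                   well_id = rep(wellIds, each = length(inoc)),
                   strain_id = rep(names(inoc), length(wellIds)),
                   initial_od = rep(unname(inoc), length(wellIds)),
                   stringsAsFactors = FALSE)
  new("PlateLayout", wells = w, inocula = il, panel = panel, seed = 0L)
}

# Single-well state with given per-strain cell counts and resources.
soloState <- function(cells, resources = c(adenine = 0, lysine = 0)) {
  structure(list(
    cells = matrix(cells, 1, dimnames = list(NULL, names(cells))),
    resources = matrix(resources, 1,
                       dimnames = list(NULL, c("adenine", "lysine"))),
    plate_id = "P1", well_id = "W01", strains = names(cells),
    time_h = 0), class = "WellState")
}
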