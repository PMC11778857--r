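#' Identify sink populations eligible for directed dispersal
#'
#' A sink is a (well, strain) pair in a dispersal-allowed well whose weekly
#' colony count is between 1 and the very-weak boundary (19 by default, the
#' "< 20 colonies" extinction trajectory). Strains already extinct (0
#' colonies) are not rescue-eligible unless \code{rescueExtinct = TRUE}:
#' reintroduction targets strains that are going extinct, not gone.
#'
#' @param scores one week's scoring table (columns \code{plate_id},
#'   \code{well_id}, \code{strain_id}, \code{colony_count}).
#' @param layout the \code{\link{PlateLayout}}.
#' @param thresholds scoring thresholds.
#' @param rescueExtinct logical; include strains at 0 colonies?
#' @return data.frame with columns \code{plate_id}, \code{well_id},
#'   \code{strain_id}, \code{colony_count}.
#' @export
findSinks <- function(scores, layout, thresholds = scoreThresholds(),
                      rescueExtinct = FALSE) {
  w <- wells(layout)
  key <- paste(w$plate_id, w$well_id)
  treatment <- w$treatment[match(paste(scores$plate_id, scores$well_id),
                                 key)]
  lo <- if (rescueExtinct) 0L else 1L
  sel <- treatment == "dispersal_allowed" &
    scores$colony_count >= lo &
    scores$colony_count <= thresholds$veryWeakMax
  scores[sel, c("plate_id", "well_id", "strain_id", "colony_count"),
         drop = FALSE]
}

#' Choose a source community for a sink strain
#'
#' Sources are drawn uniformly at random (using the current RNG stream) from
#' the dispersal-allowed wells of the same plate, excluding the sink itself,
#' in which the strain scores \code{strong} this week. Cross-plate rescue is
#' never attempted.
#'
#' @param strain strain identifier.
#' @param sinkWell sink well identifier.
#' @param plate plate identifier shared by sink and source.
#' @param scores one week's scoring table.
#' @param layout the \code{\link{PlateLayout}}.
#' @return a well identifier, or \code{NULL} if no candidate exists.
#' @export
findSource <- function(strain, sinkWell, plate, scores, layout) {
  w <- wells(layout)
  allowed <- w$well_id[w$plate_id == plate &
                         w$treatment == "dispersal_allowed"]
  cand <- scores$well_id[scores$plate_id == plate &
                           scores$strain_id == strain &
                           scores$score == "strong" &
                           scores$well_id %in% allowed &
                           scores$well_id != sinkWell]
  if (!length(cand)) return(NULL)
  cand[sample.int(length(cand), 1L)]
}

#' Apply one directed-dispersal inoculum to a sink community
#'
#' The reintroduced amount is 10\% of the average strain density in the sink
#' community right after transfer. "Average" is by default the mean over the
#' strains actually present (density > 0), so a community reduced to two
#' strains gets an inoculum matched to the density of an actual resident;
#' \code{meanOverPresent = FALSE} averages over all panel strains instead.
#'
#' @param densities named numeric vector, post-transfer per-strain densities
#'   of the sink (any consistent unit).
#' @param strain the strain being reintroduced.
#' @param fraction inoculum as a fraction of the mean density (0.10).
#' @param meanOverPresent see Description.
#' @return \code{list(densities, inoculum)} with the strain topped up, or
#'   \code{NULL} (with a warning) if the mean density is not positive.
#' @examples
#' applyDispersal(c(A = 1000, B = 3000, C = 0, D = 2000), "C")$inoculum # 200
#' @export
applyDispersal <- function(densities, strain, fraction = 0.10,
                           meanOverPresent = TRUE) {
  stopifnot(strain %in% names(densities), all(densities >= 0))
  base <- if (meanOverPresent) densities[densities > 0] else densities
  m <- if (length(base)) mean(base) else 0
  if (!is.finite(m) || m <= 0) {
    warning("sink community has no positive mean density; event skipped")
    return(NULL)
  }
  inoc <- fraction * m
  densities[strain] <- densities[strain] + inoc
  list(densities = densities, inoculum = inoc)
}

#' Did a reintroduced strain recover?
#'
#' A dispersal event counts as recovered when the strain reaches high
#' density — scores \code{strong} — in the sink well when plated two days
#' after reintroduction.
#'
#' @param event one-row data.frame with \code{plate_id}, \code{sink_well},
#'   \code{strain_id}.
#' @param followUp scoring table from two days after the event.
#' @return logical.
#' @export
checkRecovery <- function(event, followUp) {
  hit <- followUp$plate_id == event$plate_id &
    followUp$well_id == event$sink_well &
    followUp$strain_id == event$strain_id
  if (!any(hit)) stop("no follow-up observation for the event's sink strain")
  followUp$score[which(hit)[1L]] == "strong"
}

#' Recovery proportions by community type, with a permutation test
#'
#' Computes the proportion of recovered dispersal events per group and, when
#' both groups are present, a two-sided permutation test of the difference in
#' proportions obtained by shuffling group labels over events (a
#' design-light substitute for mixed-model inference on the recovery odds).
#'
#' @param recovered logical vector, one entry per dispersal event.
#' @param group factor or character grouping (e.g. community type).
#' @param nPerm number of label permutations.
#' @param seed integer seed.
#' @return list with \code{proportions}, \code{difference}, \code{p_perm}
#'   (NA when only one group is present), \code{n}.
#' @export
recoveryProportion <- function(recovered, group, nPerm = 9999L, seed = 1L) {
  stopifnot(length(recovered) == length(group))
  keep <- !is.na(recovered)
  recovered <- recovered[keep]; group <- as.character(group)[keep]
  if (!length(recovered)) stop("no assessed dispersal events")
  props <- tapply(recovered, group, mean)
  props <- stats::setNames(as.vector(props), names(props))
  n <- tapply(recovered, group, length)
  n <- stats::setNames(as.vector(n), names(n))
  if (length(props) < 2L)
    return(list(proportions = props, difference = NA_real_,
                p_perm = NA_real_, n = n))
  if (length(props) > 2L) stop("recoveryProportion expects two groups")
  obs <- props[1L] - props[2L]
  rng <- localRNG(as.integer(seed))
  on.exit(rng$restore(), add = TRUE)
  g1 <- sum(group == names(props)[1L])
  hits <- 0L
  x <- as.numeric(recovered)
  for (i in seq_len(nPerm)) {
    idx <- sample.int(length(x), g1)
    d <- mean(x[idx]) - mean(x[-idx])
    if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  list(proportions = props, difference = unname(obs),
       p_perm = (hits + 1L) / (nPerm + 1L), n = n)
}
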