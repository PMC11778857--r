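#' Read a long-format observation table
#'
#' Reads and validates a delimited observation table with required columns
#' \code{week}, \code{plate_id}, \code{well_id}, \code{strain_id},
#' \code{colony_count}, \code{score}. Unknown columns are preserved and
#' ignored. Malformed rows are reported by row number.
#'
#' @param path CSV file path.
#' @return validated data.frame (possibly empty, with a warning).
#' @export
readObservationTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty observation file: ", path)
    return(data.frame(week = integer(0), plate_id = character(0),
                      well_id = character(0), strain_id = character(0),
                      colony_count = integer(0), score = character(0),
                      stringsAsFactors = FALSE))
  }
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateObservationTable(obs)
  obs
}

#' Validate an observation table
#'
#' @param obs data.frame to check.
#' @return invisibly \code{TRUE}; stops with row-level diagnostics otherwise.
#' @export
validateObservationTable <- function(obs) {
  need <- c("week", "plate_id", "well_id", "strain_id", "colony_count",
            "score")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!nrow(obs)) {
    warning("observation table has zero rows")
    return(invisible(TRUE))
  }
  bad <- which(!is.finite(obs$colony_count) | obs$colony_count < 0 |
                 obs$colony_count != round(obs$colony_count))
  if (length(bad))
    stop("invalid colony_count on row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(!obs$score %in% .SCORES)
  if (length(bad))
    stop("malformed score label on row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which((obs$colony_count == 0) != (obs$score == "gone"))
  if (length(bad))
    stop("score inconsistent with colony_count on row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  invisible(TRUE)
}

#' @rdname readObservationTable
#' @param obs observation table to write.
#' @export
writeObservationTable <- function(obs, path) {
  validateObservationTable(obs)
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / read a plate layout
#'
#' The layout travels as a flat CSV with one row per (well, strain) and
#' blank wells carried as rows with an empty strain: columns
#' \code{plate_id}, \code{well_id}, \code{community_type}, \code{treatment},
#' \code{strain_id}, \code{initial_od}.
#'
#' @param layout a \code{\link{PlateLayout}}.
#' @param path CSV file path.
#' @export
writeLayout <- function(layout, path) {
  w <- wells(layout)
  inoc <- inocula(layout)
  key <- paste(w$plate_id, w$well_id)
  idx <- match(paste(inoc$plate_id, inoc$well_id), key)
  full <- data.frame(plate_id = inoc$plate_id, well_id = inoc$well_id,
                     community_type = w$community_type[idx],
                     treatment = w$treatment[idx],
                     strain_id = inoc$strain_id,
                     initial_od = inoc$initial_od,
                     stringsAsFactors = FALSE)
  blanks <- w[w$treatment == "blank", , drop = FALSE]
  if (nrow(blanks)) {
    full <- rbind(full, data.frame(
      plate_id = blanks$plate_id, well_id = blanks$well_id,
      community_type = blanks$community_type, treatment = blanks$treatment,
      strain_id = NA_character_, initial_od = NA_real_,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(full, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLayout
#' @param panel strain panel the layout refers to.
#' @param seed seed recorded in the returned object.
#' @export
readLayout <- function(path, panel = strainPanel(), seed = NA_integer_) {
  full <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well_id", "community_type", "treatment",
            "strain_id", "initial_od")
  miss <- setdiff(need, names(full))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  w <- unique(full[, c("plate_id", "well_id", "community_type",
                       "treatment")])
  rownames(w) <- NULL
  inoc <- full[!is.na(full$strain_id) & full$strain_id != "",
               c("plate_id", "well_id", "strain_id", "initial_od")]
  rownames(inoc) <- NULL
  new("PlateLayout", wells = w, inocula = inoc, panel = panel,
      seed = as.integer(seed))
}

#' Read a run configuration (YAML or JSON)
#'
#' Reads a configuration file and merges it over \code{\link{defaultConfig}},
#' so partial configurations are valid; the growth and scoring blocks are
#' re-validated through their constructors.
#'
#' @param path file ending in \code{.yaml}/\code{.yml} or \code{.json};
#'   \code{NULL} returns the defaults.
#' @param seed seed overriding the file's (and default's) seed, if not NA.
#' @return nested configuration list.
#' @export
readConfig <- function(path = NULL, seed = NA_integer_) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.na(seed)) cfg$seed <- as.integer(seed)
  cfg$growth <- do.call(growthParams, cfg$growth)
  cfg$scoring <- do.call(scoreThresholds, cfg$scoring)
  cfg$abundanceMap <- as.list(do.call(
    scoreAbundanceMap,
    cfg$abundanceMap[c("micro", "very_weak", "weak", "strong")]))
  cfg
}

#' @rdname readConfig
#' @param config configuration list to write.
#' @export
writeConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a run bit-identically: the full
#' configuration and its MD5 hash, the seed, and tool versions.
#'
#' @param dir output directory.
#' @param config configuration list.
#' @param extra named list of additional fields.
#' @return path of the manifest, invisibly.
#' @export
writeManifest <- function(dir, config, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- c(list(
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("MetaMutualism")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
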