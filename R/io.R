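## Plain-text serialization. All ids in files are 0-based.

#' Write / read a community as plain text
#'
#' A community directory holds \code{presence.csv} (sparse triplets
#' \code{species_id,site_id,1}), \code{sites.csv} (site_id, environment,
#' richness), \code{species.csv} (species_id, optimum, width, abundance)
#' and \code{spec.json} (the generating parameters). Ids are 0-based.
#'
#' @param community a \code{VirtualCommunity}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCommunity <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pres <- presenceMatrix(community)
  idx <- which(pres == 1L, arr.ind = TRUE)
  utils::write.csv(
    data.frame(species_id = idx[, 1L] - 1L, site_id = idx[, 2L] - 1L,
               presence = 1L),
    file.path(dir, "presence.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(site_id = seq_len(ncol(pres)) - 1L,
               environment = envGradient(community),
               richness = presetRichness(community)),
    file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(species_id = seq_len(nrow(pres)) - 1L,
               optimum = nicheOptima(community),
               width = nicheWidths(community),
               abundance = presetAbundance(community)),
    file.path(dir, "species.csv"), row.names = FALSE)
  spec <- metadata(community)$spec
  if (!is.null(spec)) {
    jsonlite::write_json(
      list(nSites = spec@nSites, nSpecies = spec@nSpecies,
           rankAbundance = spec@rankAbundance, richness = spec@richness,
           niche = spec@niche, seed = spec@seed),
      file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname writeCommunity
#' @param dir directory written by \code{writeCommunity} (or any directory
#'   with the same layout, e.g. converted from deposited distribution
#'   data).
#' @export
readCommunity <- function(dir) {
  sites <- utils::read.csv(file.path(dir, "sites.csv"))
  species <- utils::read.csv(file.path(dir, "species.csv"))
  trip <- utils::read.csv(file.path(dir, "presence.csv"))
  nSites <- nrow(sites)
  nSpecies <- nrow(species)
  pres <- matrix(0L, nSpecies, nSites,
                 dimnames = list(sprintf("sp%04d", species$species_id),
                                 sprintf("site%04d", sites$site_id)))
  pres[cbind(trip$species_id + 1L, trip$site_id + 1L)] <- 1L
  spec <- NULL
  sj <- file.path(dir, "spec.json")
  if (file.exists(sj)) {
    j <- jsonlite::read_json(sj, simplifyVector = TRUE)
    spec <- communitySpec(j$nSites, j$nSpecies,
                          rankAbundance = j$rankAbundance,
                          richness = j$richness,
                          niche = list(height = j$niche$height,
                                       widthRule = j$niche$widthRule),
                          seed = j$seed)
  }
  se <- SummarizedExperiment(
    assays = list(presence = pres),
    rowData = DataFrame(abundance = as.integer(rowSums(pres)),
                        optimum = species$optimum, width = species$width),
    colData = DataFrame(environment = sites$environment,
                        richness = as.integer(colSums(pres))),
    metadata = list(spec = spec)
  )
  new("VirtualCommunity", se)
}

#' Write a survey design or reserve selection as JSON
#'
#' Designs serialize as \code{{R, bias_level, n_blocks, seed,
#' surveyed:[...]}} and selections as \code{{approach, target_size,
#' selected:[...], n_random_fill, seed}}, with 0-based cell ids.
#'
#' @param x a \code{SurveyDesign} or \code{ReserveSelection}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDesignJSON <- function(x, path) {
  obj <- if (is(x, "SurveyDesign")) {
    list(R = x@propSurveyed, bias_level = x@biasLevel,
         n_blocks = if (is.na(x@nBlocks)) NULL else x@nBlocks,
         seed = if (is.na(x@seed)) NULL else x@seed,
         surveyed = x@surveyed - 1L)
  } else if (is(x, "ReserveSelection")) {
    list(approach = x@approach, target_size = x@targetSize,
         selected = x@selected - 1L, n_random_fill = x@nRandomFill,
         seed = if (is.na(x@seed)) NULL else x@seed)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an observation as triplet CSV
#'
#' Rows \code{species_id,site_id,1} for every presence record within the
#' surveyed cells; site ids are global and 0-based.
#'
#' @param observation a \code{SurveyObservation}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeObservationCSV <- function(observation, path) {
  obs <- observedMatrix(observation)
  idx <- which(obs == 1L, arr.ind = TRUE)
  utils::write.csv(
    data.frame(species_id = idx[, 1L] - 1L,
               site_id = surveyedSites(observation)[idx[, 2L]] - 1L,
               presence = 1L),
    path, row.names = FALSE)
  invisible(path)
}
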