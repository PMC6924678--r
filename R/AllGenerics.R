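#' @rdname VirtualCommunity-class
#' @param x a \code{VirtualCommunity}.
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname VirtualCommunity-class
#' @export
setGeneric("envGradient", function(x) standardGeneric("envGradient"))

#' @rdname VirtualCommunity-class
#' @export
setGeneric("nicheOptima", function(x) standardGeneric("nicheOptima"))

#' @rdname VirtualCommunity-class
#' @export
setGeneric("nicheWidths", function(x) standardGeneric("nicheWidths"))

#' @rdname VirtualCommunity-class
#' @export
setGeneric("presetAbundance", function(x) standardGeneric("presetAbundance"))

#' @rdname VirtualCommunity-class
#' @export
setGeneric("presetRichness", function(x) standardGeneric("presetRichness"))

#' @rdname SurveyDesign-class
#' @param x a \code{SurveyDesign} or \code{SurveyObservation}.
#' @export
setGeneric("surveyedSites", function(x) standardGeneric("surveyedSites"))

#' @rdname SurveyObservation-class
#' @export
setGeneric("observedMatrix", function(x) standardGeneric("observedMatrix"))

#' @rdname SurveyObservation-class
#' @export
setGeneric("observedAbundance",
           function(x) standardGeneric("observedAbundance"))

#' @rdname NicheModelSet-class
#' @param x a \code{NicheModelSet}.
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' @rdname NicheModelSet-class
#' @export
setGeneric("modelStatus", function(x) standardGeneric("modelStatus"))

#' @rdname NicheModelSet-class
#' @export
setGeneric("excludedSpecies", function(x) standardGeneric("excludedSpecies"))

#' @rdname ReserveSelection-class
#' @param x a \code{ReserveSelection}.
#' @export
setGeneric("selectedSites", function(x) standardGeneric("selectedSites"))

#' Observe a community under a survey design
#'
#' Restrict the true presence matrix to the surveyed cells. Surveys are
#' error-free, so the observed submatrix equals the truth on those columns.
#'
#' @param community a \code{VirtualCommunity}.
#' @param design a \code{SurveyDesign} for the same grid.
#' @return a \code{SurveyObservation}.
#' @examples
#' sp <- communitySpec(nSites = 40, nSpecies = 15, seed = 1)
#' com <- generateCommunity(sp)
#' des <- makeSurvey(0.25, "none", nSites = 40, seed = 2)
#' obs <- observe(com, des)
#' dim(observedMatrix(obs))
#' @export
setGeneric("observe", function(community, design) standardGeneric("observe"))
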