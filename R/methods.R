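## Accessors and show() methods.

#' @rdname VirtualCommunity-class
#' @aliases presenceMatrix,VirtualCommunity-method
setMethod("presenceMatrix", "VirtualCommunity",
          function(x) assay(x, "presence"))

#' @rdname VirtualCommunity-class
setMethod("envGradient", "VirtualCommunity",
          function(x) colData(x)$environment)

#' @rdname VirtualCommunity-class
setMethod("nicheOptima", "VirtualCommunity", function(x) rowData(x)$optimum)

#' @rdname VirtualCommunity-class
setMethod("nicheWidths", "VirtualCommunity", function(x) rowData(x)$width)

#' @rdname VirtualCommunity-class
setMethod("presetAbundance", "VirtualCommunity",
          function(x) rowData(x)$abundance)

#' @rdname VirtualCommunity-class
setMethod("presetRichness", "VirtualCommunity",
          function(x) colData(x)$richness)

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:", object@nSpecies, "species x", object@nSites,
      "sites\n")
  cat("  rank-abundance:", object@rankAbundance$family, "\n")
  cat("  richness:      ", object@richness$family, "\n")
  cat(sprintf("  niche: height %.3g, width rule w = %.3g + %.3g * relAbund\n",
              object@niche$height, object@niche$widthRule[1L],
              object@niche$widthRule[2L]))
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "VirtualCommunity", function(object) {
  p <- presenceMatrix(object)
  cat("VirtualCommunity:", nrow(p), "species x", ncol(p), "sites,",
      sum(p), "presence records\n")
  cat(sprintf("  abundance range [%d, %d]; richness range [%d, %d]\n",
              min(rowSums(p)), max(rowSums(p)),
              min(colSums(p)), max(colSums(p))))
  spec <- metadata(object)$spec
  if (!is.null(spec))
    cat("  generated from seed", spec@seed, "\n")
})

#' @rdname SurveyDesign-class
setMethod("surveyedSites", "SurveyDesign", function(x) x@surveyed)

#' @rdname SurveyDesign-class
setMethod("surveyedSites", "SurveyObservation",
          function(x) x@design@surveyed)

setMethod("show", "SurveyDesign", function(object) {
  cat(sprintf("SurveyDesign: R = %.3g (%d of %d cells), bias %s",
              object@propSurveyed, length(object@surveyed), object@nSites,
              object@biasLevel))
  if (!is.na(object@nBlocks)) cat(" (", object@nBlocks, " blocks)", sep = "")
  cat("\n")
})

#' @rdname SurveyObservation-class
#' @param x a \code{SurveyObservation}.
setMethod("observedMatrix", "SurveyObservation", function(x) x@observed)

#' @rdname SurveyObservation-class
setMethod("observedAbundance", "SurveyObservation",
          function(x) x@observedAbundance)

setMethod("show", "SurveyObservation", function(object) {
  cat("SurveyObservation:", nrow(object@observed), "species x",
      ncol(object@observed), "surveyed cells;",
      sum(object@observedAbundance > 0L), "species recorded\n")
})

#' @rdname NicheModelSet-class
setMethod("probMatrix", "NicheModelSet", function(x) x@prob)

#' @rdname NicheModelSet-class
setMethod("modelStatus", "NicheModelSet", function(x) x@status)

#' @rdname NicheModelSet-class
setMethod("excludedSpecies", "NicheModelSet",
          function(x) which(x@status == "excluded_never_observed"))

setMethod("show", "NicheModelSet", function(object) {
  tab <- table(object@status)
  cat("NicheModelSet (", object@algorithm, "): ", nrow(object@prob),
      " species\n", sep = "")
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
})

#' @rdname ReserveSelection-class
setMethod("selectedSites", "ReserveSelection", function(x) x@selected)

setMethod("show", "ReserveSelection", function(object) {
  cat(sprintf("ReserveSelection (%s): %d cells (%d by random fill)\n",
              object@approach, object@targetSize, object@nRandomFill))
})
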