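#' @import methods
#' @importFrom stats plogis rnorm runif rbinom median setNames aggregate
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom Rcpp sourceCpp
#' @useDynLib nichesim, .registration = TRUE
NULL

#' Community generation parameters
#'
#' A \code{CommunitySpec} bundles every parameter that determines a virtual
#' community: grid size, species pool size, the rank-abundance and richness
#' distribution families with their parameters, the niche rule (suitability
#' height and the mapping from relative abundance to niche width), and the
#' RNG seed. It is the single source of truth for
#' \code{\link{generateCommunity}}; identical specs (including seed) produce
#' bit-identical communities.
#'
#' @slot nSites number of grid cells on the one-dimensional gradient.
#' @slot nSpecies number of species in the pool.
#' @slot rankAbundance list with elements \code{family} (one of
#'   \code{"log_linear"}, \code{"log_normal"}, \code{"empirical_table"}) and
#'   \code{parameters} (named list; see \code{\link{buildRankAbundance}}).
#' @slot richness list with elements \code{family} (one of
#'   \code{"log_linear"}, \code{"empirical_table"}) and \code{parameters}.
#' @slot niche list with elements \code{height} (suitability peak on the
#'   logit scale) and \code{widthRule} (length-2 numeric, intercept and slope
#'   of niche width against relative abundance).
#' @slot seed integer RNG seed.
#' @exportClass CommunitySpec
setClass("CommunitySpec",
  representation(
    nSites = "integer",
    nSpecies = "integer",
    rankAbundance = "list",
    richness = "list",
    niche = "list",
    seed = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  msg <- character()
  if (length(object@nSites) != 1L || is.na(object@nSites) || object@nSites < 2L)
    msg <- c(msg, "nSites must be a single integer >= 2")
  if (length(object@nSpecies) != 1L || is.na(object@nSpecies) ||
      object@nSpecies < 1L)
    msg <- c(msg, "nSpecies must be a single integer >= 1")
  for (nm in c("rankAbundance", "richness")) {
    d <- slot(object, nm)
    if (!is.list(d) || is.null(d$family))
      msg <- c(msg, sprintf("%s must be a list with a 'family' element", nm))
  }
  ok <- c("log_linear", "log_normal", "empirical_table")
  if (!is.null(object@rankAbundance$family) &&
      !object@rankAbundance$family %in% ok)
    msg <- c(msg, sprintf("unknown rank-abundance family '%s'",
                          object@rankAbundance$family))
  if (!is.null(object@richness$family) &&
      !object@richness$family %in% c("log_linear", "empirical_table"))
    msg <- c(msg, sprintf("unknown richness family '%s'",
                          object@richness$family))
  if (!is.numeric(object@niche$height) || length(object@niche$height) != 1L)
    msg <- c(msg, "niche$height must be a single number")
  wr <- object@niche$widthRule
  if (!is.numeric(wr) || length(wr) != 2L)
    msg <- c(msg, "niche$widthRule must be numeric of length 2")
  else if (wr[1L] <= 0)
    msg <- c(msg, "niche width intercept must be positive")
  if (length(msg)) msg else TRUE
})

#' Virtual community with known true distributions
#'
#' \code{VirtualCommunity} extends \code{SummarizedExperiment}: the single
#' assay \code{"presence"} is the binary species-by-site matrix,
#' \code{rowData} carries the per-species niche parameters (environmental
#' optimum, niche width) and preset abundance, and \code{colData} carries the
#' site environment values and preset richness. The generating
#' \code{CommunitySpec} is stored in \code{metadata(x)$spec}.
#'
#' Row sums of the presence matrix equal the preset abundances and column
#' sums the preset richness, exactly; this is enforced by the validity
#' method and preserved by the swap refinement.
#'
#' @exportClass VirtualCommunity
setClass("VirtualCommunity", contains = "SummarizedExperiment")

setValidity("VirtualCommunity", function(object) {
  msg <- character()
  if (!"presence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'presence' is required")
  p <- assay(object, "presence")
  if (!all(p %in% c(0L, 1L)))
    msg <- c(msg, "presence entries must be 0/1")
  rd <- rowData(object)
  cd <- colData(object)
  need_r <- c("abundance", "optimum", "width")
  if (!all(need_r %in% colnames(rd)))
    msg <- c(msg, "rowData must have columns abundance, optimum, width")
  if (!all(c("environment", "richness") %in% colnames(cd)))
    msg <- c(msg, "colData must have columns environment, richness")
  if (!length(msg)) {
    if (!all(rowSums(p) == rd$abundance))
      msg <- c(msg, "row sums must equal preset abundances")
    if (!all(colSums(p) == cd$richness))
      msg <- c(msg, "column sums must equal preset richness")
    if (is.unsorted(cd$environment, strictly = TRUE))
      msg <- c(msg, "environment must be strictly increasing")
    if (any(rd$width <= 0))
      msg <- c(msg, "niche widths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Survey design: which cells are surveyed
#'
#' The surveyed range covers \code{round(nSites * R)} cells. Under the block
#' design the grid is partitioned into \code{nBlocks} equal runs and each
#' block receives a run of consecutive surveyed cells at a uniformly random
#' position; fewer blocks means stronger spatial bias. \code{biasLevel}
#' \code{"none"} is a simple random sample of cells, \code{"weak"} uses 5
#' blocks, \code{"strong"} uses 2.
#'
#' @slot propSurveyed proportion of cells surveyed (the survey range R).
#' @slot biasLevel one of "none", "weak", "strong".
#' @slot nBlocks number of survey blocks (NA for unblocked designs).
#' @slot nSites grid size the design refers to.
#' @slot surveyed sorted integer vector of surveyed cell indices (1-based).
#' @slot seed integer seed used to draw the design.
#' @exportClass SurveyDesign
setClass("SurveyDesign",
  representation(
    propSurveyed = "numeric",
    biasLevel = "character",
    nBlocks = "integer",
    nSites = "integer",
    surveyed = "integer",
    seed = "integer"
  )
)

setValidity("SurveyDesign", function(object) {
  msg <- character()
  if (object@propSurveyed <= 0 || object@propSurveyed > 1)
    msg <- c(msg, "propSurveyed must be in (0, 1]")
  if (!object@biasLevel %in% c("none", "weak", "strong"))
    msg <- c(msg, "biasLevel must be none, weak or strong")
  if (anyDuplicated(object@surveyed))
    msg <- c(msg, "surveyed cells must be distinct")
  if (is.unsorted(object@surveyed))
    msg <- c(msg, "surveyed cells must be sorted")
  if (length(object@surveyed) &&
      (min(object@surveyed) < 1L || max(object@surveyed) > object@nSites))
    msg <- c(msg, "surveyed indices out of range")
  if (length(object@surveyed) != round(object@nSites * object@propSurveyed))
    msg <- c(msg, "number of surveyed cells must equal round(nSites * R)")
  if (length(msg)) msg else TRUE
})

#' Error-free observation of a community under a survey design
#'
#' Surveys are error-free: the observed matrix is the true presence matrix
#' restricted to the surveyed columns.
#'
#' @slot design the \code{SurveyDesign}.
#' @slot observed binary matrix, species by surveyed cells.
#' @slot observedAbundance integer vector of presences per species within
#'   the survey.
#' @exportClass SurveyObservation
setClass("SurveyObservation",
  representation(
    design = "SurveyDesign",
    observed = "matrix",
    observedAbundance = "integer"
  )
)

#' Fitted niche models for every observed species
#'
#' One presence/absence model per species observed at least once in the
#' survey, and the predicted probability of presence over all cells. Species
#' never observed in the survey range cannot be modelled and are excluded;
#' their probability rows are NA and their status is
#' \code{"excluded_never_observed"}. Species with no absences among surveyed
#' cells get a constant predictor (status \code{"degenerate_constant"}).
#'
#' @slot algorithm one of "glm", "gam", "rf", "oracle".
#' @slot status character vector, per species: "fitted",
#'   "excluded_never_observed", "degenerate_constant", or a fallback tag.
#' @slot prob numeric matrix species x sites of predicted presence
#'   probabilities; NA rows for excluded species.
#' @slot fitMeta per-species diagnostics (data.frame).
#' @exportClass NicheModelSet
setClass("NicheModelSet",
  representation(
    algorithm = "character",
    status = "character",
    prob = "matrix",
    fitMeta = "data.frame"
  )
)

setValidity("NicheModelSet", function(object) {
  msg <- character()
  if (nrow(object@prob) != length(object@status))
    msg <- c(msg, "one status per species (row of prob) required")
  excl <- object@status == "excluded_never_observed"
  pr <- object@prob[!excl, , drop = FALSE]
  if (length(pr) && (anyNA(pr) || any(pr < 0) || any(pr > 1)))
    msg <- c(msg, "probabilities of non-excluded species must be in [0,1]")
  if (any(!is.na(object@prob[excl, , drop = FALSE])))
    msg <- c(msg, "excluded species must have all-NA probability rows")
  if (length(msg)) msg else TRUE
})

#' A selected reserve network
#'
#' An ordered set of cells of fixed target size chosen by one of the two
#' greedy approaches; cells added by random fill (when the greedy phase
#' stops early) come after the greedy cells in the order.
#'
#' @slot approach "raw" or "enm".
#' @slot targetSize number of cells selected.
#' @slot selected ordered integer vector of selected cell indices (1-based).
#' @slot nRandomFill how many trailing cells were added by random fill.
#' @slot seed seed used for the random fill (NA if none).
#' @exportClass ReserveSelection
setClass("ReserveSelection",
  representation(
    approach = "character",
    targetSize = "integer",
    selected = "integer",
    nRandomFill = "integer",
    seed = "integer"
  )
)

setValidity("ReserveSelection", function(object) {
  msg <- character()
  if (!object@approach %in% c("raw", "enm"))
    msg <- c(msg, "approach must be 'raw' or 'enm'")
  if (length(object@selected) != object@targetSize)
    msg <- c(msg, "length(selected) must equal targetSize")
  if (anyDuplicated(object@selected))
    msg <- c(msg, "selected cells must be distinct")
  if (object@nRandomFill > object@targetSize)
    msg <- c(msg, "nRandomFill cannot exceed targetSize")
  if (length(msg)) msg else TRUE
})
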