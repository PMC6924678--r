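## Virtual surveys: survey range R and spatial bias via the block design.

.biasBlocks <- c(none = NA_integer_, weak = 5L, strong = 2L)

#' Draw a survey design
#'
#' Exactly \code{round(nSites * R)} cells are surveyed. With bias
#' (\code{"weak"} = 5 blocks, \code{"strong"} = 2 blocks) the grid is
#' divided into equal blocks and each block receives a run of
#' \code{nSites*R/nBlocks} consecutive surveyed cells at a uniformly random
#' position within the block; when the quota is indivisible, the remainder
#' cells are assigned one each to randomly chosen blocks. With
#' \code{"none"} the surveyed cells are a simple random sample of the grid,
#' the maximally even limit of the block design.
#'
#' @param R proportion of cells surveyed, in (0, 1].
#' @param biasLevel "none", "weak" or "strong".
#' @param nSites grid size.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @param nBlocks override the number of blocks implied by
#'   \code{biasLevel}.
#' @return a \code{\link{SurveyDesign}}.
#' @examples
#' makeSurvey(0.05, "strong", nSites = 1000, seed = 3)
#' @export
makeSurvey <- function(R, biasLevel = c("none", "weak", "strong"),
                       nSites, seed = NULL, nBlocks = NULL) {
  biasLevel <- match.arg(biasLevel)
  if (R <= 0 || R > 1) stop("R must be in (0, 1]")
  nSites <- as.integer(nSites)
  nCells <- as.integer(round(nSites * R))
  if (nCells < 1L) stop("round(nSites * R) must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nBlocks)) nBlocks <- .biasBlocks[[biasLevel]]
  nBlocks <- as.integer(nBlocks)

  if (is.na(nBlocks)) {
    surveyed <- sort(sample.int(nSites, nCells))
  } else {
    if (nSites %% nBlocks != 0L)
      stop("number of blocks must divide nSites")
    blockSize <- nSites %/% nBlocks
    quota <- rep(nCells %/% nBlocks, nBlocks)
    rem <- nCells - sum(quota)
    if (rem > 0L) {
      extra <- sample.int(nBlocks, rem)
      quota[extra] <- quota[extra] + 1L
    }
    if (any(quota > blockSize))
      stop("per-block quota exceeds block size")
    surveyed <- unlist(lapply(seq_len(nBlocks), function(b) {
      q <- quota[b]
      if (q == 0L) return(integer())
      start <- sample.int(blockSize - q + 1L, 1L)
      (b - 1L) * blockSize + start + seq_len(q) - 1L
    }))
    surveyed <- sort(as.integer(surveyed))
  }
  new("SurveyDesign", propSurveyed = R, biasLevel = biasLevel,
      nBlocks = nBlocks, nSites = nSites, surveyed = surveyed,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname observe
setMethod("observe", signature("VirtualCommunity", "SurveyDesign"),
  function(community, design) {
    pres <- presenceMatrix(community)
    if (design@nSites != ncol(pres))
      stop("design grid size does not match the community")
    if (max(design@surveyed) > ncol(pres))
      stop("surveyed index out of range")
    sub <- pres[, design@surveyed, drop = FALSE]
    new("SurveyObservation", design = design, observed = sub,
        observedAbundance = as.integer(rowSums(sub)))
  })
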