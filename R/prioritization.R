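## Greedy maximal-coverage reserve selection: raw-data and ENM approaches.

#' Greedy reserve selection from raw survey records
#'
#' Implements the raw-data approach under the maximal-coverage target.
#' Starting from the surveyed cell with the largest observed species
#' richness, cells adding the most not-yet-covered recorded species are
#' selected step by step, ties broken by lowest cell index. The greedy
#' phase ends when the target size is reached or when every recorded
#' species is covered; any shortfall is filled with uniformly random cells
#' from the unsurveyed range (and, only if that range is exhausted, from
#' the remaining surveyed cells).
#'
#' @param observation a \code{SurveyObservation}.
#' @param targetSize number of cells to select.
#' @param seed optional seed for the random fill.
#' @return a \code{\link{ReserveSelection}} with \code{approach = "raw"}.
#' @export
greedyRaw <- function(observation, targetSize, seed = NULL) {
  targetSize <- as.integer(targetSize)
  design <- observation@design
  nSites <- design@nSites
  if (targetSize > nSites) stop("targetSize exceeds the number of sites")
  if (!is.null(seed)) set.seed(seed)
  obs <- observedMatrix(observation)
  surveyed <- surveyedSites(observation)   # sorted ascending

  covered <- rep(FALSE, nrow(obs))
  avail <- rep(TRUE, length(surveyed))     # local columns still selectable
  sel <- integer(0)
  while (length(sel) < targetSize && any(avail)) {
    gains <- colSums(obs[!covered, avail, drop = FALSE])
    if (!length(gains) || max(gains) == 0L) break
    jloc <- which(avail)[which.max(gains)]  # ties -> lowest cell index
    sel <- c(sel, surveyed[jloc])
    covered <- covered | (obs[, jloc] == 1L)
    avail[jloc] <- FALSE
  }
  nGreedy <- length(sel)

  if (length(sel) < targetSize) {
    unsurveyed <- setdiff(seq_len(nSites), surveyed)
    need <- targetSize - length(sel)
    take <- min(need, length(unsurveyed))
    if (take > 0L)
      sel <- c(sel, sample(unsurveyed, take))
    if (length(sel) < targetSize) {
      rest <- setdiff(surveyed, sel)
      sel <- c(sel, sample(rest, targetSize - length(sel)))
    }
  }
  new("ReserveSelection", approach = "raw", targetSize = targetSize,
      selected = as.integer(sel),
      nRandomFill = as.integer(targetSize - nGreedy),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Expected number of species represented in a cell set
#'
#' Under independent presence probabilities \code{p[s, i]}, the expected
#' number of species with at least one presence among the cells is
#' \code{sum_s (1 - prod_i (1 - p[s, i]))}. Species with all-NA rows
#' (excluded, never observed) contribute nothing.
#'
#' @param prob probability matrix, species by sites (or a
#'   \code{NicheModelSet}).
#' @param cells integer vector of cell indices.
#' @return expected species count.
#' @examples
#' p <- rbind(c(0.5, 0.5), c(1, 0))
#' expectedRichness(p, c(1, 2))  # 1.75
#' @export
expectedRichness <- function(prob, cells) {
  if (is(prob, "NicheModelSet")) prob <- probMatrix(prob)
  if (length(cells) == 0L) return(0)
  if (any(cells < 1L | cells > ncol(prob))) stop("cell index out of range")
  p <- prob[rowSums(is.na(prob)) == 0L, cells, drop = FALSE]
  sum(1 - exp(rowSums(log1p(-p))))
}

#' Greedy reserve selection maximizing expected species coverage
#'
#' The ENM approach: cells are added one at a time to maximize the marginal
#' gain in expected species coverage, \code{sum_s r_s * p[s, j]}, where
#' \code{r_s} is the running probability that species \code{s} is still
#' uncovered by the cells already selected. Deterministic; ties broken by
#' lowest cell index. As expected coverage is monotone submodular, the
#' greedy value is within a factor \code{1 - 1/e} of the optimum.
#'
#' @param models a \code{NicheModelSet} or a probability matrix (NA rows
#'   are treated as excluded species).
#' @param targetSize number of cells to select.
#' @return a \code{\link{ReserveSelection}} with \code{approach = "enm"}.
#' @export
greedyExpected <- function(models, targetSize) {
  prob <- if (is(models, "NicheModelSet")) probMatrix(models) else models
  targetSize <- as.integer(targetSize)
  if (targetSize > ncol(prob)) stop("targetSize exceeds the number of sites")
  P <- prob[rowSums(is.na(prob)) == 0L, , drop = FALSE]
  if (nrow(P) == 0L)
    stop("no non-excluded species: cannot run the expected-coverage greedy")
  r <- rep(1, nrow(P))
  avail <- rep(TRUE, ncol(P))
  sel <- integer(targetSize)
  for (step in seq_len(targetSize)) {
    gains <- drop(r %*% P[, avail, drop = FALSE])
    jloc <- which(avail)[which.max(gains)]
    sel[step] <- jloc
    r <- r * (1 - P[, jloc])
    avail[jloc] <- FALSE
  }
  new("ReserveSelection", approach = "enm", targetSize = targetSize,
      selected = sel, nRandomFill = 0L, seed = NA_integer_)
}

#' Number of species truly covered by a cell set
#'
#' Counts species with at least one true presence among the cells,
#' including species that were never observed in any survey but happen to
#' fall inside the selected area.
#'
#' @param community a \code{VirtualCommunity}.
#' @param cells integer cell indices (or a \code{ReserveSelection}).
#' @return integer species count.
#' @export
speciesCovered <- function(community, cells) {
  if (is(cells, "ReserveSelection")) cells <- selectedSites(cells)
  if (length(cells) == 0L) return(0L)
  pres <- presenceMatrix(community)
  if (any(cells < 1L | cells > ncol(pres))) stop("cell index out of range")
  sum(rowSums(pres[, cells, drop = FALSE]) > 0L)
}
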