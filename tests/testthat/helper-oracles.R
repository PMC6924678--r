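# Brute-force oracles and small fixtures, independent of the package's own
# algorithms.

smallSpec <- function(nSites = 60L, nSpecies = 30L, seed = 1L, ...) {
  communitySpec(nSites = nSites, nSpecies = nSpecies, seed = seed, ...)
}

# all binary matrices with the given row sums (abundance) and column sums
# (richness), by exhaustive recursion over rows
enumerateMargins <- function(abundance, richness) {
  nSites <- length(richness)
  out <- list()
  recur <- function(rowIdx, cap, acc) {
    if (rowIdx > length(abundance)) {
      if (all(cap == 0L)) out[[length(out) + 1L]] <<- do.call(rbind, acc)
      return(invisible())
    }
    a <- abundance[rowIdx]
    for (cols in utils::combn(nSites, a, simplify = FALSE)) {
      if (any(cap[cols] == 0L)) next
      cap2 <- cap
      cap2[cols] <- cap2[cols] - 1L
      row <- integer(nSites)
      row[cols] <- 1L
      recur(rowIdx + 1L, cap2, c(acc, list(row)))
    }
  }
  recur(1L, as.integer(richness), list())
  out
}

# exhaustive optimum of sum(logS * M) over all margin-preserving matrices
bruteSwapOptimum <- function(abundance, richness, logS) {
  mats <- enumerateMargins(abundance, richness)
  max(vapply(mats, function(m) sum(logS * m), numeric(1)))
}

# exhaustive optimum of expected richness over all k-subsets of cells
bruteExpectedOptimum <- function(prob, k) {
  subsets <- utils::combn(ncol(prob), k, simplify = FALSE)
  max(vapply(subsets, function(cells) {
    sum(1 - apply(1 - prob[, cells, drop = FALSE], 1, prod))
  }, numeric(1)))
}

# pairwise-concordance AUC, counting ties one half (brute force)
bruteAUC <- function(prob, truth) {
  pos <- prob[truth == 1]
  neg <- prob[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# quick valid community for prioritization/evaluation tests
testCommunity <- function(nSites = 40L, nSpecies = 20L, seed = 7L) {
  generateCommunity(smallSpec(nSites, nSpecies, seed))
}

# wrap an arbitrary 0/1 matrix into a valid VirtualCommunity
.makeToyCommunity <- function(pres) {
  pres <- matrix(as.integer(pres), nrow(pres), ncol(pres))
  n <- ncol(pres)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = pres),
    rowData = S4Vectors::DataFrame(
      abundance = as.integer(rowSums(pres)),
      optimum = runif(nrow(pres)),
      width = rep(0.2, nrow(pres))),
    colData = S4Vectors::DataFrame(
      environment = if (n > 1) (seq_len(n) - 1) / (n - 1) else 0,
      richness = as.integer(colSums(pres))))
  new("VirtualCommunity", se)
}

# all non-increasing integer tuples of a given length with entries in lo:hi
sortedTuples <- function(len, lo, hi) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == len) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq(min(mx, hi), lo)) rec(c(prefix, as.integer(v)), v)
  }
  rec(integer(0), hi)
  out
}

galeRyserFeasible <- function(ab, rich) {
  tryCatch({
    nichesim:::.galeRyserCheck(ab, rich)
    TRUE
  }, error = function(e) FALSE)
}
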