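## Effectiveness evaluation and the factorial sweep.

#' Effectiveness index of the ENM approach
#'
#' \code{coveredEnm / coveredRaw - 1}: greater than zero exactly when the
#' ENM-based reserve covers more species than the raw-data reserve. When
#' the raw-data reserve covers no species at all the index is undefined and
#' returned as NA with a warning.
#'
#' @param coveredEnm,coveredRaw species counts covered by the two
#'   approaches.
#' @return a real number, or NA when \code{coveredRaw} is zero.
#' @examples
#' effectivenessIndex(60, 50)  # 0.2
#' @export
effectivenessIndex <- function(coveredEnm, coveredRaw) {
  if (coveredEnm < 0 || coveredRaw < 0) stop("species counts cannot be negative")
  if (coveredRaw == 0) {
    warning("raw-data reserve covers no species; effectiveness undefined")
    return(NA_real_)
  }
  coveredEnm / coveredRaw - 1
}

#' Rare-species coverage of a reserve
#'
#' Rare species are those with fewer than \code{threshold} true presence
#' records. Returns the number of covered species that are rare and the
#' ratio of rare species among all covered species (0 when nothing is
#' covered).
#'
#' @param community a \code{VirtualCommunity}.
#' @param selection a \code{ReserveSelection} or a vector of cell indices.
#' @param threshold rarity cutoff on true abundance (default 20).
#' @return list with \code{coveredRare} and \code{rareRatio}.
#' @export
rareSpeciesMetrics <- function(community, selection, threshold = 20L) {
  stopifnot(threshold >= 1L)
  cells <- if (is(selection, "ReserveSelection"))
    selectedSites(selection) else as.integer(selection)
  pres <- presenceMatrix(community)
  cov <- if (length(cells)) rowSums(pres[, cells, drop = FALSE]) > 0L
         else rep(FALSE, nrow(pres))
  rare <- presetAbundance(community) < threshold
  nCov <- sum(cov)
  nRare <- sum(cov & rare)
  list(coveredRare = as.integer(nRare),
       rareRatio = if (nCov == 0L) 0 else nRare / nCov)
}

#' Derive a reproducible sub-seed from a master seed and a factor tuple
#'
#' Hashes the master seed together with arbitrary labels into an integer in
#' \code{[1, 2^31 - 2]}, so that every cell of a factorial design consumes
#' an independent, independently reproducible random stream.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a single integer seed.
#' @export
deriveSeed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, character(1))),
               collapse = "|")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

#' Execute one factorial cell: survey, model, select, evaluate
#'
#' Runs the whole pipeline on an existing community for one combination of
#' survey range, survey bias, target size and modelling algorithm: draw the
#' survey, observe, fit the niche models, build both reserve selections
#' from the same observation (paired design), and score both against the
#' true distributions. All randomness is derived from \code{masterSeed} via
#' \code{\link{deriveSeed}}, with the survey sub-seed depending only on
#' (R, bias) so that different targets and algorithms see the identical
#' observation.
#'
#' @param community a \code{VirtualCommunity}.
#' @param R survey range, proportion of cells surveyed.
#' @param biasLevel "none", "weak" or "strong".
#' @param targetProportion reserve size as a proportion of the grid.
#' @param algorithm "glm", "gam", "rf" or "oracle".
#' @param masterSeed integer seed for the cell.
#' @param config model tuning settings (see \code{\link{fitNicheModels}}).
#' @param rareThreshold rarity cutoff (default 20 presence records).
#' @param cache optional environment used by \code{\link{runSweep}} to
#'   share observations and fitted models across cells that are guaranteed
#'   (by their sub-seeds) to be identical.
#' @return one-row data.frame with the factors, the coverage metrics, the
#'   effectiveness indices, rare-species metrics, mean AUC over modelled
#'   species, and the number of excluded species.
#' @export
runOne <- function(community, R, biasLevel, targetProportion, algorithm,
                   masterSeed, config = list(), rareThreshold = 20L,
                   cache = NULL) {
  nSites <- ncol(presenceMatrix(community))
  targetSize <- as.integer(round(targetProportion * nSites))

  surveySeed <- deriveSeed(masterSeed, "survey", R, biasLevel)
  obs <- .cached(cache, paste0("obs", surveySeed), {
    observe(community, makeSurvey(R, biasLevel, nSites, seed = surveySeed))
  })

  fitSeed <- deriveSeed(masterSeed, "fit", R, biasLevel, algorithm)
  models <- .cached(cache, paste0("fit", algorithm, fitSeed), {
    fitNicheModels(community, obs, algorithm, config, seed = fitSeed)
  })

  rawSeed <- deriveSeed(masterSeed, "rawfill", R, biasLevel,
                        targetProportion)
  rawSel <- greedyRaw(obs, targetSize, seed = rawSeed)
  coveredRaw <- speciesCovered(community, rawSel)
  rareRaw <- rareSpeciesMetrics(community, rawSel, rareThreshold)

  anyModelled <- any(modelStatus(models) != "excluded_never_observed")
  if (anyModelled) {
    enmSel <- greedyExpected(models, targetSize)
    coveredEnm <- speciesCovered(community, enmSel)
    rareEnm <- rareSpeciesMetrics(community, enmSel, rareThreshold)
  } else {
    warning("no species observed; ENM approach not applicable in this cell")
    coveredEnm <- NA_integer_
    rareEnm <- list(coveredRare = NA_integer_, rareRatio = NA_real_)
  }

  eff <- if (is.na(coveredEnm)) NA_real_ else {
    if (coveredRaw == 0) suppressWarnings(
      effectivenessIndex(coveredEnm, coveredRaw))
    else effectivenessIndex(coveredEnm, coveredRaw)
  }
  effRare <- if (is.na(rareEnm$coveredRare) || rareRaw$coveredRare == 0L)
    NA_real_ else rareEnm$coveredRare / rareRaw$coveredRare - 1

  truth <- presenceMatrix(community)
  prob <- probMatrix(models)
  aucs <- vapply(which(modelStatus(models) != "excluded_never_observed"),
                 function(s) computeAUC(prob[s, ], truth[s, ]), numeric(1))
  meanAuc <- if (length(aucs)) mean(aucs, na.rm = TRUE) else NA_real_

  data.frame(
    R = R, bias_level = biasLevel, target_proportion = targetProportion,
    algorithm = algorithm, master_seed = masterSeed,
    covered_raw = coveredRaw, covered_enm = coveredEnm,
    effectiveness = eff,
    covered_rare_raw = rareRaw$coveredRare,
    covered_rare_enm = rareEnm$coveredRare,
    rare_ratio_raw = rareRaw$rareRatio, rare_ratio_enm = rareEnm$rareRatio,
    effectiveness_rare = effRare,
    mean_auc = meanAuc,
    n_excluded_species = length(excludedSpecies(models)),
    stringsAsFactors = FALSE
  )
}

.cached <- function(cache, key, expr) {
  if (is.null(cache)) return(expr)
  if (!exists(key, envir = cache, inherits = FALSE))
    assign(key, expr, envir = cache)
  get(key, envir = cache, inherits = FALSE)
}

#' Configure a factorial sweep
#'
#' Assembles and checks the factor levels of a sweep. The defaults are the
#' full canonical design: three community structure types (log-linear,
#' log-normal, and an empirical-table type using a synthetic stand-in
#' occupancy table), 10 replicate communities per type, 19 survey ranges
#' from 0.05 to 0.95, three bias levels, five target sizes (1.0, 2.5, 5.0,
#' 9.1 and 17 percent of the grid) and three modelling algorithms —
#' 25,650 runs in total.
#'
#' @param communitySpecs named list of \code{CommunitySpec} objects, one
#'   per community structure type (each spec's own seed is overridden by a
#'   replicate-specific seed derived from \code{masterSeed}).
#' @param nReplicates replicate communities per type (default 10).
#' @param RValues survey ranges (default \code{seq(0.05, 0.95, by = 0.05)}).
#' @param biasLevels subset of c("none", "weak", "strong").
#' @param targetProportions reserve sizes as proportions (default
#'   \code{c(0.010, 0.025, 0.050, 0.091, 0.170)}).
#' @param algorithms subset of c("glm", "gam", "rf").
#' @param masterSeed master seed from which every cell's randomness is
#'   derived.
#' @param rareThreshold rarity cutoff.
#' @param modelConfig tuning settings passed to
#'   \code{\link{fitNicheModels}}.
#' @param nSites,nSpecies grid and pool sizes used for the default
#'   community specs (ignored when \code{communitySpecs} is supplied).
#' @return a list of class \code{"sweepConfig"}.
#' @export
sweepConfig <- function(communitySpecs = NULL,
                        nReplicates = 10L,
                        RValues = seq(0.05, 0.95, by = 0.05),
                        biasLevels = c("none", "weak", "strong"),
                        targetProportions = c(0.010, 0.025, 0.050,
                                              0.091, 0.170),
                        algorithms = c("glm", "gam", "rf"),
                        masterSeed = 1L,
                        rareThreshold = 20L,
                        modelConfig = list(),
                        nSites = 1000L, nSpecies = 1000L) {
  if (is.null(communitySpecs)) {
    communitySpecs <- list(
      log_linear = communitySpec(nSites, nSpecies,
        rankAbundance = list(family = "log_linear", parameters = list())),
      log_normal = communitySpec(nSites, nSpecies,
        rankAbundance = list(family = "log_normal", parameters = list())),
      empirical = communitySpec(nSites, nSpecies,
        rankAbundance = list(
          family = "empirical_table",
          parameters = list(table = syntheticOccupancyTable(nSites))))
    )
  }
  if (is.null(names(communitySpecs)) || any(names(communitySpecs) == ""))
    names(communitySpecs) <- paste0("type", seq_along(communitySpecs))
  stopifnot(all(vapply(communitySpecs, is, logical(1), "CommunitySpec")),
            all(biasLevels %in% c("none", "weak", "strong")),
            all(algorithms %in% c("glm", "gam", "rf", "oracle")),
            all(RValues > 0 & RValues <= 1),
            all(targetProportions > 0 & targetProportions <= 1))
  structure(list(communitySpecs = communitySpecs,
                 nReplicates = as.integer(nReplicates),
                 RValues = RValues, biasLevels = biasLevels,
                 targetProportions = targetProportions,
                 algorithms = algorithms,
                 masterSeed = as.integer(masterSeed),
                 rareThreshold = as.integer(rareThreshold),
                 modelConfig = modelConfig),
            class = "sweepConfig")
}

#' Synthetic occupancy frequency table with an excess of rare species
#'
#' A small built-in stand-in for empirical occupancy (presence-sites per
#' species) frequency tables digitized from survey reports: most species
#' occupy very few cells and a thin tail is widespread, the shape commonly
#' reported for real assemblages. Values scale with the grid size.
#'
#' @param nSites grid size the table should span.
#' @return data.frame with columns \code{value} and \code{frequency}.
#' @export
syntheticOccupancyTable <- function(nSites = 1000L) {
  frac <- c(0.001, 0.002, 0.004, 0.008, 0.016, 0.03, 0.06, 0.1,
            0.18, 0.3, 0.45, 0.6)
  value <- unique(pmax(1L, as.integer(round(frac * nSites))))
  data.frame(value = value,
             frequency = round(1000 * seq_along(value)^-1.6))
}

#' Enumerate the cells of a factorial sweep
#'
#' Returns the full factorial plan — one row per (community type,
#' replicate, R, bias, target, algorithm) combination — without executing
#' anything.
#'
#' @param config a \code{\link{sweepConfig}}.
#' @return data.frame with one row per run.
#' @examples
#' nrow(sweepPlan(sweepConfig()))  # 25650
#' @export
sweepPlan <- function(config) {
  stopifnot(inherits(config, "sweepConfig"))
  plan <- expand.grid(
    target_proportion = config$targetProportions,
    algorithm = config$algorithms,
    R = config$RValues,
    bias_level = config$biasLevels,
    replicate = seq_len(config$nReplicates),
    community_type = names(config$communitySpecs),
    stringsAsFactors = FALSE
  )
  plan[, c("community_type", "replicate", "R", "bias_level",
           "target_proportion", "algorithm")]
}

#' Run a factorial sweep
#'
#' Generates \code{nReplicates} communities per community type (each from a
#' seed derived from the master seed, so any replicate can be regenerated
#' independently) and executes \code{\link{runOne}} for every cell of the
#' plan. The same replicate community is reused across all survey, target
#' and algorithm factors, and within a replicate the observation and the
#' fitted models are shared across cells whose sub-seeds make them
#' identical. Optionally resumable: with \code{resumeFile}, completed rows
#' are appended to a CSV as they finish and already-present rows are
#' skipped on restart.
#'
#' @param config a \code{\link{sweepConfig}}.
#' @param resumeFile optional CSV path for checkpointing.
#' @param verbose print per-community progress to stderr.
#' @return data.frame, one row per run (the plan columns plus the metrics
#'   of \code{\link{runOne}}).
#' @export
runSweep <- function(config, resumeFile = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweepConfig"))
  plan <- sweepPlan(config)
  done <- NULL
  if (!is.null(resumeFile) && file.exists(resumeFile)) {
    done <- utils::read.csv(resumeFile, stringsAsFactors = FALSE)
  }
  keyOf <- function(d) paste(d$community_type, d$replicate, d$R,
                             d$bias_level, d$target_proportion,
                             d$algorithm, sep = "~")
  doneKeys <- if (is.null(done)) character(0) else keyOf(done)

  rows <- vector("list", nrow(plan))
  groups <- split(seq_len(nrow(plan)),
                  paste(plan$community_type, plan$replicate, sep = "~"),
                  drop = FALSE)
  # iterate communities in plan order
  groups <- groups[unique(paste(plan$community_type, plan$replicate,
                                sep = "~"))]
  for (g in groups) {
    type <- plan$community_type[g[1L]]
    rep_ <- plan$replicate[g[1L]]
    idxTodo <- g[!(keyOf(plan[g, ]) %in% doneKeys)]
    if (!length(idxTodo)) next
    spec <- config$communitySpecs[[type]]
    spec@seed <- deriveSeed(config$masterSeed, "community", type, rep_)
    if (verbose)
      message(sprintf("community %s replicate %d (%d cells) ...",
                      type, rep_, length(idxTodo)))
    com <- generateCommunity(spec)
    cellMaster <- deriveSeed(config$masterSeed, "cell", type, rep_)
    cache <- new.env(parent = emptyenv())
    for (i in idxTodo) {
      rec <- runOne(com, plan$R[i], plan$bias_level[i],
                    plan$target_proportion[i], plan$algorithm[i],
                    masterSeed = cellMaster, config = config$modelConfig,
                    rareThreshold = config$rareThreshold, cache = cache)
      rec <- cbind(plan[i, c("community_type", "replicate")], rec,
                   row.names = NULL)
      rows[[i]] <- rec
      if (!is.null(resumeFile))
        utils::write.table(rec, resumeFile, sep = ",", append =
                           file.exists(resumeFile), row.names = FALSE,
                           col.names = !file.exists(resumeFile))
    }
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(done)) res <- rbind(done, res)
  res <- res[order(match(keyOf(res), keyOf(plan))), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "config") <- config
  res
}

#' Summarize a sweep: percentage of beneficial cases and medians
#'
#' For each group of the results table, the percentage of runs in which
#' the effectiveness index (or its rare-species variant) exceeds zero —
#' the criterion for the ENM approach being beneficial — together with the
#' median effectiveness and counts. Runs with undefined effectiveness
#' (raw coverage zero) are excluded from the percentage denominator and
#' reported in \code{n_missing}. Include \code{"R"} in \code{groupby} to
#' obtain the per-survey-range curves.
#'
#' @param results data.frame from \code{\link{runSweep}}.
#' @param groupby character vector of factor columns.
#' @param rare use \code{effectiveness_rare} instead of
#'   \code{effectiveness}.
#' @return data.frame with one row per group: \code{n}, \code{n_missing},
#'   \code{pct_beneficial}, \code{median_effectiveness}.
#' @export
summarizeSweep <- function(results,
                           groupby = c("bias_level", "target_proportion"),
                           rare = FALSE) {
  if (!nrow(results)) stop("empty results table")
  if (!all(groupby %in% names(results)))
    stop("unknown grouping factor(s): ",
         paste(setdiff(groupby, names(results)), collapse = ", "))
  eff <- if (rare) results$effectiveness_rare else results$effectiveness
  keys <- results[, groupby, drop = FALSE]
  grp <- interaction(keys, drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(grp), function(lv) {
    i <- grp == lv
    e <- eff[i]
    cbind(unique(keys[i, , drop = FALSE])[1, , drop = FALSE],
          data.frame(n = sum(i), n_missing = sum(is.na(e)),
                     pct_beneficial = 100 * mean(e > 0, na.rm = TRUE),
                     median_effectiveness = median(e, na.rm = TRUE)))
  }))
  rownames(out) <- NULL
  out
}
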