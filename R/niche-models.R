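## Per-species niche models: quadratic-logit GLM, spline GAM, random forest.

.defaultModelConfig <- function(config = list()) {
  def <- list(
    gamK = 10L,            # max basis dimension of the cubic spline
    rfTrees = 500L,        # trees in the final forest
    rfTuneTrees = 150L,    # trees per forest while tuning node size
    rfNodeSizes = c(1L, 5L, 10L, 25L),
    ridge = 1e-4,          # fallback penalty for separated GLMs
    probClip = 1e-9        # keep model probabilities off exact 0/1
  )
  def[names(config)] <- config
  def
}

# Ridge-penalized logistic regression by Newton iteration on the raw
# (unstandardized) design; used only as a separation/non-convergence
# fallback with a tiny fixed penalty on the non-intercept coefficients.
.ridgeLogit <- function(X, y, lambda, maxit = 100L) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))), ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * w) + pen
    g <- crossprod(X1, y - mu) - pen %*% beta
    step <- drop(solve(H, g))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' Fit one species' niche model
#'
#' Fits a presence/absence model of a single species on the surveyed cells
#' and returns a predictor function of the environment. Algorithms:
#' \describe{
#'   \item{glm}{binomial GLM, logit link, linear + quadratic terms of the
#'     environment — the same functional form used to generate the
#'     suitabilities. On separation or non-convergence the model is refit
#'     with a small ridge penalty; if that also fails, a constant-prevalence
#'     predictor is used (noted in the metadata).}
#'   \item{gam}{binomial GAM with a penalized cubic regression spline;
#'     basis dimension \code{min(gamK, #distinct env values - 1)}. Falls
#'     back to the quadratic GLM when too few distinct environments.}
#'   \item{rf}{probability random forest of \code{rfTrees} trees on the
#'     single covariate; minimum terminal node size tuned by out-of-bag
#'     error over \code{rfNodeSizes}.}
#' }
#' A species with presences at every surveyed cell has no absences to
#' contrast and receives a constant predictor equal to its observed
#' prevalence (1), with status \code{"degenerate_constant"}. Calling this
#' function with zero presences is a contract violation: such species must
#' be excluded by the caller.
#'
#' @param algorithm "glm", "gam" or "rf".
#' @param envSurveyed environment values of the surveyed cells.
#' @param y binary presence/absence vector over surveyed cells.
#' @param config list of tuning settings; see
#'   \code{\link{fitNicheModels}}.
#' @return list with elements \code{predict} (function env -> probability),
#'   \code{status}, and \code{meta} (diagnostics).
#' @export
fitSpeciesModel <- function(algorithm, envSurveyed, y, config = list()) {
  cfg <- .defaultModelConfig(config)
  y <- as.integer(y)
  if (length(y) != length(envSurveyed))
    stop("y and envSurveyed must have equal length")
  nPres <- sum(y)
  if (nPres == 0L)
    stop("species with zero presences must be excluded, not fitted")
  if (nPres == length(y)) {
    return(list(predict = function(e) rep(1, length(e)),
                status = "degenerate_constant",
                meta = list(nPresence = nPres, note = "all-presence")))
  }
  switch(algorithm,
    glm = .fitGlm(envSurveyed, y, cfg),
    gam = .fitGam(envSurveyed, y, cfg),
    rf = .fitRf(envSurveyed, y, cfg),
    stop("unknown algorithm '", algorithm, "'")
  )
}

.fitGlm <- function(e, y, cfg) {
  X <- cbind(e = e, e2 = e^2)
  # extreme but genuine fitted probabilities are fine; only refuse the ML
  # fit on non-convergence or runaway coefficients (separation)
  fit <- try(suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial())),
    silent = TRUE)
  ok <- !inherits(fit, "try-error") && fit$converged &&
    all(is.finite(fit$coefficients)) && max(abs(fit$coefficients)) < 1e4
  if (ok) {
    beta <- fit$coefficients
    note <- "ml"
  } else {
    beta <- try(.ridgeLogit(X, y, cfg$ridge), silent = TRUE)
    if (inherits(beta, "try-error") || !all(is.finite(beta))) {
      prev <- mean(y)
      return(list(predict = function(ee) rep(prev, length(ee)),
                  status = "fitted",
                  meta = list(nPresence = sum(y),
                              note = "constant-prevalence fallback")))
    }
    note <- "ridge fallback"
  }
  b <- unname(beta)
  list(predict = function(ee) plogis(b[1] + b[2] * ee + b[3] * ee^2),
       status = "fitted",
       meta = list(nPresence = sum(y), note = note, coef = b))
}

.fitGam <- function(e, y, cfg) {
  k <- min(cfg$gamK, length(unique(e)) - 1L)
  if (k < 3L) {
    out <- .fitGlm(e, y, cfg)
    out$meta$note <- paste("glm fallback (too few distinct env);",
                           out$meta$note)
    return(out)
  }
  d <- data.frame(y = y, e = e)
  fit <- try(suppressWarnings(
    mgcv::gam(y ~ s(e, k = k, bs = "cr"), family = stats::binomial(),
              data = d)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- .fitGlm(e, y, cfg)
    out$meta$note <- paste("glm fallback (gam failed);", out$meta$note)
    return(out)
  }
  list(predict = function(ee)
         as.numeric(stats::predict(fit, newdata = data.frame(e = ee),
                                   type = "response")),
       status = "fitted",
       meta = list(nPresence = sum(y), note = "gam", k = k))
}

.fitRf <- function(e, y, cfg) {
  d <- data.frame(y = factor(y, levels = c(0L, 1L)), e = e)
  sizes <- cfg$rfNodeSizes[cfg$rfNodeSizes <= length(y)]
  if (!length(sizes)) sizes <- 1L
  oob <- vapply(sizes, function(ns) {
    ranger::ranger(y ~ e, data = d, probability = TRUE,
                   num.trees = cfg$rfTuneTrees, min.node.size = ns,
                   num.threads = 1L)$prediction.error
  }, numeric(1))
  best <- sizes[which.min(oob)]
  fit <- ranger::ranger(y ~ e, data = d, probability = TRUE,
                        num.trees = cfg$rfTrees, min.node.size = best,
                        num.threads = 1L)
  list(predict = function(ee)
         stats::predict(fit, data = data.frame(e = ee),
                        num.threads = 1L)$predictions[, "1"],
       status = "fitted",
       meta = list(nPresence = sum(y), note = "rf",
                   min.node.size = best, oob = min(oob)))
}

#' Predict presence probabilities over all sites
#'
#' Evaluates each species' predictor at every site environment and clips
#' the result into [0, 1].
#'
#' @param models list of per-species predictors as returned by
#'   \code{\link{fitSpeciesModel}} (NULL entries for excluded species).
#' @param envAll environment values of all sites.
#' @return numeric matrix, species by sites; NA rows for NULL entries.
#' @export
predictProbabilities <- function(models, envAll) {
  prob <- matrix(NA_real_, length(models), length(envAll))
  for (s in seq_along(models)) {
    if (is.null(models[[s]])) next
    prob[s, ] <- pmin(pmax(models[[s]]$predict(envAll), 0), 1)
  }
  prob
}

#' Fit niche models for every observed species
#'
#' Fits one model per species with at least one presence record in the
#' survey and predicts over the whole grid. Species never observed in the
#' survey range are excluded — no model can be constructed for them — and
#' get all-NA probability rows. Predicted probabilities are clipped away
#' from exact 0 and 1 (by \code{probClip}) so that the expected-coverage
#' greedy never locks a species' residual probability at zero because of a
#' numerically saturated prediction. \code{algorithm = "oracle"} bypasses
#' fitting and uses the true presence/absence values as probabilities
#' (unclipped), for perfect-knowledge baselines.
#'
#' @param community the \code{VirtualCommunity} (supplies site environments
#'   and, for the oracle, the truth).
#' @param observation a \code{SurveyObservation} of that community.
#' @param algorithm "glm", "gam", "rf" or "oracle".
#' @param config tuning settings, see \code{\link{fitSpeciesModel}};
#'   entries: \code{gamK}, \code{rfTrees}, \code{rfTuneTrees},
#'   \code{rfNodeSizes}, \code{ridge}, \code{probClip}.
#' @param seed optional seed for the stochastic fitting steps (random
#'   forest bootstraps).
#' @return a \code{\link{NicheModelSet}}.
#' @export
fitNicheModels <- function(community, observation,
                           algorithm = c("glm", "gam", "rf", "oracle"),
                           config = list(), seed = NULL) {
  algorithm <- match.arg(algorithm)
  cfg <- .defaultModelConfig(config)
  if (!is.null(seed)) set.seed(seed)
  envAll <- envGradient(community)
  obs <- observedMatrix(observation)
  nSpecies <- nrow(obs)
  obsAb <- observedAbundance(observation)

  if (algorithm == "oracle") {
    prob <- presenceMatrix(community) * 1.0
    prob[obsAb == 0L, ] <- NA_real_
    status <- ifelse(obsAb == 0L, "excluded_never_observed", "fitted")
    meta <- data.frame(species = seq_len(nSpecies), status = status,
                       nPresence = obsAb, note = "oracle")
    return(new("NicheModelSet", algorithm = algorithm, status = status,
               prob = prob, fitMeta = meta))
  }

  envSurv <- envAll[surveyedSites(observation)]
  models <- vector("list", nSpecies)
  status <- rep("excluded_never_observed", nSpecies)
  notes <- rep(NA_character_, nSpecies)
  for (s in which(obsAb > 0L)) {
    m <- fitSpeciesModel(algorithm, envSurv, obs[s, ], config)
    models[[s]] <- m
    status[s] <- m$status
    notes[s] <- m$meta$note
  }
  prob <- predictProbabilities(models, envAll)
  keep <- status != "excluded_never_observed"
  prob[keep, ] <- pmin(pmax(prob[keep, , drop = FALSE], cfg$probClip),
                       1 - cfg$probClip)
  meta <- data.frame(species = seq_len(nSpecies), status = status,
                     nPresence = obsAb, note = notes)
  new("NicheModelSet", algorithm = algorithm, status = status,
      prob = prob, fitMeta = meta)
}

#' Rank-based AUC of predicted probabilities against the truth
#'
#' Mann-Whitney AUC with the midrank convention for ties: the probability
#' that a randomly chosen true presence is scored above a randomly chosen
#' true absence, counting ties one half. Undefined (NA) when the truth is
#' all presence or all absence.
#'
#' @param prob numeric vector of predicted probabilities.
#' @param truth binary vector of true presence/absence.
#' @return AUC in [0, 1], or NA when undefined.
#' @examples
#' computeAUC(c(0.9, 0.2, 0.6, 0.4), c(1, 0, 1, 0))  # 1
#' @export
computeAUC <- function(prob, truth) {
  if (length(prob) != length(truth))
    stop("prob and truth must have equal length")
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
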