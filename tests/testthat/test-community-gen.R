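test_that("log-linear rank-abundance follows its functional form", {
  set.seed(1)
  spec <- list(family = "log_linear",
               parameters = list(intercept = log(500), slope = 0.006))
  ab <- buildRankAbundance(spec, nSpecies = 1000L, nSites = 1000L)
  expect_length(ab, 1000L)
  expect_true(all(ab >= 1L & ab <= 1000L))
  # log(abundance) vs rank is linear with slope -a, up to rounding:
  # compare against the exact curve before rounding
  expect_true(all(abs(ab - exp(log(500) - 0.006 * (0:999))) <= 0.5 + 1e-9))
  # degenerate single species
  spec1 <- list(family = "log_linear",
                parameters = list(intercept = log(20), slope = 0.1))
  ab1 <- buildRankAbundance(spec1, nSpecies = 1L, nSites = 50L)
  expect_length(ab1, 1L)
  expect_true(ab1 >= 1L && ab1 <= 50L)
})

test_that("log-normal abundances match a brute-force resampling oracle", {
  set.seed(42)
  spec <- list(family = "log_normal",
               parameters = list(meanlog = 3, sdlog = 1.2))
  ab <- buildRankAbundance(spec, nSpecies = 1000L, nSites = 1000L)
  # oracle: independent large resample with the same round-and-clamp
  set.seed(4242)
  ref <- pmin(pmax(floor(exp(rnorm(2e5, 3, 1.2)) + 0.5), 1), 1000)
  ks <- suppressWarnings(stats::ks.test(log(ab), log(ref)))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("infeasible rank-abundance parameters are rejected", {
  spec <- list(family = "log_linear",
               parameters = list(intercept = log(5000), slope = 1e-4))
  expect_error(buildRankAbundance(spec, 1000L, 1000L), "infeasible")
  expect_error(
    buildRankAbundance(list(family = "weibull", parameters = list()),
                       10L, 10L), "unknown")
})

test_that("richness draws respect bounds and are exchangeable across sites", {
  set.seed(3)
  spec <- list(family = "log_linear",
               parameters = list(slope = 0.05, min = 0L, max = 100L))
  rich <- buildRichness(spec, nSites = 2000L, nSpecies = 100L)
  expect_length(rich, 2000L)
  expect_true(all(rich >= 0L & rich <= 100L))
  # frequency distribution is log-linear: log counts of adjacent values
  # decrease by ~slope (checked loosely on well-populated values)
  cnt <- tabulate(rich + 1L, 31L)
  fit <- stats::lm(log(cnt) ~ I(0:30))
  expect_equal(unname(stats::coef(fit)[2]), -0.05, tolerance = 0.25)
  # no spatial structure: first vs second half have similar means
  expect_equal(mean(rich[1:1000]), mean(rich[1001:2000]), tolerance = 0.1)
  # point-mass empirical table gives a constant vector
  const <- buildRichness(list(family = "empirical_table",
                              parameters = list(
                                table = data.frame(value = 7,
                                                   frequency = 1))),
                         nSites = 25L, nSpecies = 50L)
  expect_equal(const, rep(7L, 25L))
})

test_that("margin reconciliation equalizes totals by unit richness moves", {
  set.seed(9)
  ab <- c(3L, 2L, 1L)
  rich <- c(2L, 2L, 2L)  # equal sums: untouched
  m <- reconcileMargins(ab, rich)
  expect_identical(m$richness, rich)
  expect_identical(m$abundance, ab)

  rich2 <- c(1L, 1L, 1L, 1L, 1L, 0L)  # sum 5, abundance sums 6+
  ab2 <- c(5L, 3L, 2L)                # sum 10: add 5 to richness
  m2 <- reconcileMargins(ab2, rich2)
  expect_equal(sum(m2$richness), sum(ab2))
  expect_true(all(m2$richness >= rich2))       # only increments
  expect_true(all(m2$richness <= 3L))          # bounded by nSpecies

  # downward adjustment
  m3 <- reconcileMargins(c(1L, 1L), c(2L, 2L, 2L))
  expect_equal(sum(m3$richness), 2L)
  expect_true(all(m3$richness >= 0L))
})

test_that("reconciled random margins are Gale-Ryser feasible and realizable", {
  set.seed(11)
  nOk <- 0L
  while (nOk < 100L) {
    nSp <- sample(2:6, 1)
    nSi <- sample(3:6, 1)
    ab <- sample.int(nSi, nSp, replace = TRUE)
    rich <- sample(0:nSp, nSi, replace = TRUE)
    # random tiny margin pairs may be unrealizable even after totals agree;
    # those must error cleanly, realizable ones must round-trip exactly
    m <- tryCatch(reconcileMargins(ab, rich, nSpecies = nSp),
                  error = function(e) {
                    expect_match(conditionMessage(e), "Gale-Ryser")
                    NULL
                  })
    if (is.null(m)) next
    nOk <- nOk + 1L
    pres <- initialAssignment(m$abundance, m$richness)
    expect_identical(unname(rowSums(pres)), as.numeric(m$abundance))
    expect_identical(unname(colSums(pres)), as.numeric(m$richness))
  }
})

test_that("infeasible margins are refused with the violated inequality", {
  # sums equal (4) but one species needs 3 of 2 usable columns:
  # ab sorted = (3,1); k=1: 3 > min(r,1) summed = 1+1+0 -> violation
  expect_error(reconcileMargins(c(3L, 1L), c(2L, 2L, 0L)), "Gale-Ryser")
  expect_error(reconcileMargins(c(5L, 1L), c(2L, 2L, 2L)), "\\[1, nSites\\]")
})

test_that("niche widths are positive and monotone in abundance", {
  set.seed(2)
  n <- assignNiches(c(10L, 500L), nSites = 1000L, widthRule = c(0.05, 0.5))
  expect_true(all(n$widths > 0))
  expect_gte(n$widths[2], n$widths[1])
  # zero slope: all widths equal the intercept
  n0 <- assignNiches(c(1L, 99L, 500L), 1000L, widthRule = c(0.2, 0))
  expect_equal(n0$widths, rep(0.2, 3))
  expect_error(assignNiches(c(1L), 10L, widthRule = c(-0.1, 0)),
               "non-positive")
})

test_that("niche optima are uniform over the gradient (KS against oracle)", {
  set.seed(5)
  n <- assignNiches(rep(10L, 5000L), nSites = 100L)
  ks <- suppressWarnings(stats::ks.test(n$optima, "punif"))$statistic
  expect_lt(unname(ks), 0.03)
})

test_that("suitability is the inverse-logit of the shifted quadratic", {
  expect_equal(suitability(0.5, c = 0.5, w = 0.1, h = 2), plogis(2))
  # symmetry about the optimum
  d <- runif(20, 0, 0.3)
  expect_equal(suitability(0.4 + d, 0.4, 0.07, 1.5),
               suitability(0.4 - d, 0.4, 0.07, 1.5))
  # closed form at one width from the optimum, h = 0
  expect_equal(suitability(0.3, c = 0.2, w = 0.1, h = 0), plogis(-1))
  expect_equal(plogis(-1), 0.2689, tolerance = 1e-3)
  # unimodal with maximum at e = c
  e <- seq(0, 1, length.out = 101)
  s <- suitability(e, 0.37, 0.1, 2)
  expect_equal(e[which.max(s)], 0.37)
  expect_error(suitability(0.5, 0.5, -1, 2))
})

test_that("initial assignment hits forced realizations and exact margins", {
  set.seed(8)
  # single species occupying everything: forced all-ones row
  pres <- initialAssignment(4L, rep(1L, 4L))
  expect_equal(unname(pres), matrix(1L, 1, 4))
  # exact margins across many seeds
  for (i in 1:50) {
    ab <- c(4L, 2L, 1L)
    rich <- c(2L, 2L, 1L, 1L, 1L, 0L)
    pres <- initialAssignment(ab, rich)
    expect_identical(unname(rowSums(pres)), as.numeric(ab))
    expect_identical(unname(colSums(pres)), as.numeric(rich))
  }
})

test_that("initial assignment reaches every realization of small margins", {
  # margins ab = (2, 1), rich = (1, 1, 1): exactly 3 realizations
  mats <- enumerateMargins(c(2L, 1L), c(1L, 1L, 1L))
  expect_length(mats, 3L)
  set.seed(123)
  seen <- integer(3)
  for (i in 1:600) {
    pres <- initialAssignment(c(2L, 1L), c(1L, 1L, 1L))
    hit <- which(vapply(mats, function(m) all(m == pres), logical(1)))
    seen[hit] <- seen[hit] + 1L
  }
  expect_true(all(seen > 0L))
  # roughly balanced: no realization is vanishingly rare
  chi <- suppressWarnings(stats::chisq.test(seen))
  expect_gt(chi$p.value, 1e-4)
})

test_that("swap refinement preserves margins and never decreases the objective", {
  set.seed(21)
  for (i in 1:10) {
    nSp <- 12L; nSi <- 15L
    ab <- sample.int(8L, nSp, replace = TRUE)
    rich <- sample(0:6, nSi, replace = TRUE)
    m <- reconcileMargins(ab, rich, nSp)
    env <- (seq_len(nSi) - 1) / (nSi - 1)
    opt <- runif(nSp); wid <- 0.05 + 0.5 * m$abundance / nSi
    pres <- initialAssignment(m$abundance, m$richness)
    before <- swapObjective(pres, env, opt, wid, 2)
    ref <- refineBySwapping(pres, env, opt, wid, 2)
    expect_identical(unname(rowSums(ref)), as.numeric(m$abundance))
    expect_identical(unname(colSums(ref)), as.numeric(m$richness))
    expect_gte(swapObjective(ref, env, opt, wid, 2), before)
  }
})

test_that("a local optimum is a fixed point of the refinement", {
  # two specialists at opposite ends of a 4-site gradient, already sorted:
  # no improving swap exists
  env <- c(0, 1/3, 2/3, 1)
  opt <- c(0, 1); wid <- c(0.3, 0.3)
  pres <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  ref <- refineBySwapping(pres, env, opt, wid, 2, maxConsecRej = 5000L)
  expect_equal(unname(ref), unname(pres), ignore_attr = TRUE)
})

test_that("refinement of anti-sorted specialists reaches the brute-force optimum", {
  env <- c(0, 1/3, 2/3, 1)
  opt <- c(0, 1); wid <- c(0.3, 0.3)
  logS <- log(outer(seq_along(opt), seq_along(env),
                    function(s, i) suitability(env[i], opt[s], wid[s], 2)))
  best <- bruteSwapOptimum(c(2L, 2L), c(1L, 1L, 1L, 1L), logS)
  pres <- rbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))  # anti-sorted
  set.seed(31)
  ref <- refineBySwapping(pres, env, opt, wid, 2, maxConsecRej = 5000L)
  expect_equal(sum(logS * ref), best)
  # each specialist now occupies the sites nearest its optimum
  expect_equal(unname(ref), rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)),
               ignore_attr = TRUE)
})

test_that("generation is deterministic given the spec and seed", {
  spec <- smallSpec(50L, 25L, seed = 77L)
  c1 <- generateCommunity(spec)
  c2 <- generateCommunity(spec)
  expect_identical(presenceMatrix(c1), presenceMatrix(c2))
  expect_identical(nicheOptima(c1), nicheOptima(c2))
  c3 <- generateCommunity(smallSpec(50L, 25L, seed = 78L))
  expect_false(identical(presenceMatrix(c1), presenceMatrix(c3)))
})

test_that("refinement improves the preference objective on random specs", {
  worse <- 0L
  for (s in 1:15) {
    spec <- smallSpec(40L, 20L, seed = 1000L + s)
    raw <- generateCommunity(spec, refine = FALSE)
    ref <- generateCommunity(spec)
    env <- envGradient(ref)
    h <- metadata(ref)$spec@niche$height
    o0 <- swapObjective(presenceMatrix(raw), env, nicheOptima(raw),
                        nicheWidths(raw), h)
    o1 <- swapObjective(presenceMatrix(ref), env, nicheOptima(ref),
                        nicheWidths(ref), h)
    if (o1 < o0) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("refined communities carry an environmental signal", {
  spec <- smallSpec(80L, 40L, seed = 5L)
  raw <- generateCommunity(spec, refine = FALSE)
  ref <- generateCommunity(spec)
  env <- envGradient(ref)
  occMean <- function(com) {
    p <- presenceMatrix(com)
    as.numeric(p %*% env) / rowSums(p)
  }
  keep <- presetAbundance(ref) < ncol(presenceMatrix(ref)) / 2
  rhoRef <- suppressWarnings(
    stats::cor(occMean(ref)[keep], nicheOptima(ref)[keep],
               method = "spearman"))
  rhoRaw <- suppressWarnings(
    stats::cor(occMean(raw)[keep], nicheOptima(raw)[keep],
               method = "spearman"))
  expect_gt(rhoRef, 0)
  expect_gt(rhoRef, rhoRaw)
})
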