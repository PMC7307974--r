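test_that("zFullConditional follows the two-component odds arithmetic", {
  expect_equal(zFullConditional(-5, -5, 0.95), 0.95)
  expect_equal(zFullConditional(-5, -5, 0.2), 0.2)
  expect_equal(zFullConditional(log(19) - 3, -3, 0.5), 0.95)
  expect_equal(zFullConditional(-Inf, -3, 0.9), 0)
  expect_equal(zFullConditional(-3, -Inf, 0.1), 1)
  # numerically stable far into the tails
  expect_equal(zFullConditional(-1e6, -1e6 + log(19), 0.5), 0.05)
  expect_error(zFullConditional(0, 0, 1), "inside")
})

test_that("allocation full conditional matches joint enumeration", {
  # 5-area, 4-time model with all other parameters frozen: enumerate the
  # joint over all 2^5 allocation vectors and compare the implied marginals
  set.seed(10)
  N <- 5; T <- 4
  E <- matrix(runif(N * T, 20, 80), N, T)
  muC <- matrix(rnorm(N * T, 0, 0.2), N, T)
  muAS <- muC + matrix(rnorm(N * T, 0, 0.2), N, T)
  Y <- matrix(rpois(N * T, E * exp(mixtureLinpred(c(1, 1, 0, 1, 0), muC, muAS))), N, T)
  prior <- 0.95

  llR <- function(mu) sapply(1:N, function(i)
    sum(dpois(Y[i, ], E[i, ] * exp(mu[i, ]), log = TRUE)))
  LC <- llR(muC); LAS <- llR(muAS)

  configs <- as.matrix(expand.grid(rep(list(0:1), N)))
  logw <- apply(configs, 1, function(z) {
    sum(z * LC + (1 - z) * LAS) + sum(z * log(prior) + (1 - z) * log(1 - prior))
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  marginal <- unname(colSums(configs * w))

  expect_equal(zFullConditional(LC, LAS, prior), marginal, tolerance = 1e-10)

  # Monte-Carlo: Gibbs draws from the full conditional reproduce the
  # enumerated marginals
  set.seed(11)
  p <- zFullConditional(LC, LAS, prior)
  draws <- matrix(rbinom(N * 4000, 1, p), ncol = N, byrow = TRUE)
  expect_equal(colMeans(draws), marginal, tolerance = 0.03)
})

test_that("gelmanRubin separates mixed from unmixed chains", {
  set.seed(12)
  x <- rnorm(500)
  expect_lt(gelmanRubin(cbind(x, x)), 1 + 1e-8)
  mixed <- matrix(rnorm(2000), ncol = 2)
  expect_lt(gelmanRubin(mixed), 1.05)
  apart <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(gelmanRubin(apart), 3)
  # hand-computed PSRF on a 2-chain, 4-draw toy array:
  # W = 5/3, B = 2, varPlus = 7/4, PSRF = sqrt(21/20)
  expect_equal(gelmanRubin(cbind(0:3, 1:4)), sqrt(1.75 / (5 / 3)))
  expect_error(gelmanRubin(matrix(1:4, ncol = 1)), "two chains")
})

test_that("mcError behaves like a batch-means standard error", {
  expect_equal(mcError(rep(2.5, 400)), 0)
  set.seed(13)
  x <- rnorm(10000)
  expect_equal(mcError(x, 20), 1 / sqrt(10000), tolerance = 0.5)
  expect_true(is.finite(mcError(x, 10)))
  expect_error(mcError(x, 1), ">= 2")
})

test_that("the sampler is reproducible and allocates strong common data to the Common model", {
  set.seed(14)
  g <- latticeGraph(2, 2)
  d <- flatDataset(4, 5, E = 100)
  fit1 <- runMCMC(d, g, "baseline", shortConfig(seed = 3))
  fit2 <- runMCMC(d, g, "baseline", shortConfig(seed = 3))
  expect_identical(allocationProb(fit1), allocationProb(fit2))
  expect_identical(fit1@draws, fit2@draws)
  fit3 <- runMCMC(d, g, "baseline", shortConfig(seed = 4))
  expect_false(identical(allocationProb(fit1), allocationProb(fit3)))

  # data generated under a shared flat surface: every area should lean Common
  expect_true(all(allocationProb(fit1) > 0.5))

  fitP <- runMCMC(d, g, "proposed", shortConfig(seed = 3))
  expect_true(all(allocationProb(fitP) >= 0))
  expect_identical(dim(allocationProb(fitP)), c(4L, 5L))
})

test_that("adapted Metropolis blocks settle at moderate acceptance rates", {
  set.seed(15)
  g <- latticeGraph(3, 3)
  spec <- scenarioSpec("S2", nUnusualAreas = 2, seed = 8, T = 10)
  sim <- simulateScenario(spec, g)
  fit <- runMCMC(sim, g, "proposed", shortConfig(nIter = 2000, seed = 2))
  rates <- fit@acceptanceRates
  rates <- rates[!is.na(rates)]
  expect_true(all(rates >= 0.1 & rates <= 0.6),
              info = paste(names(rates), round(rates, 2), collapse = ", "))
})

test_that("MCMC configuration files round-trip through DCF", {
  path <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("nIter: 1000", "burnIn: 400", "nChains: 3", "seed: 42"), path)
  cfg <- readMCMCConfig(path)
  expect_identical(cfg$nIter, 1000L)
  expect_identical(cfg$burnIn, 400L)
  expect_identical(cfg$nChains, 3L)
  expect_identical(cfg$thin, 2L)  # default retained
  expect_true(cfg$adapt)
  writeLines("wibble: 3", path)
  expect_error(readMCMCConfig(path), "unknown config field")
})

test_that("invalid inputs to runMCMC are rejected", {
  g <- latticeGraph(2, 2)
  d <- flatDataset(4, 5)
  expect_error(runMCMC(d, latticeGraph(3, 3), "baseline", shortConfig()),
               "one node per area")
  expect_error(mcmcConfig(nIter = 100, burnIn = 100), "burnIn")
  expect_error(mcmcConfig(thin = 0), "thin")
})
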