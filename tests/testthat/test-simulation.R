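test_that("scenario specs encode the study design table", {
  s5 <- scenarioSpec("S5", seed = 1)
  expect_identical(s5$spatialPattern, "clustered")
  expect_identical(s5$temporalPattern, "consecutive_variable")
  expect_identical(s5$T, 15L)
  expect_identical(s5$nUnusualAreas, 15L)
  expect_identical(s5$nSims, 50L)

  expect_identical(scenarioSpec("S7", seed = 1)$T, 30L)
  expect_identical(scenarioSpec("S8", seed = 1)$expectedScale, 2)
  expect_identical(scenarioSpec("S9", seed = 1)$expectedScale, 0.5)
  s10 <- scenarioSpec("S10", seed = 1, nUnusualAreas = 5)
  expect_identical(s10$nUnusualAreas, 0L)
  expect_error(scenarioSpec("S1", expectedScale = 0), "positive")
})

test_that("the Common surface has the stated prior moments", {
  g <- latticeGraph(4, 4)
  set.seed(30)
  flat <- generateCommonSurface(g, 10,
    hyper = list(alpha0 = 0.2, sigma2V = 0.1, sigma2Eta = 0.01,
                 sigma2Gamma = 0))
  expect_equal(flat$gamma, rep(0, 10))
  expect_equal(flat$alpha0, 0.2)
  expect_equal(sum(flat$v), 0, tolerance = 1e-10)

  # RW1 increments of gamma have variance sigma2Gamma (Monte-Carlo moment)
  set.seed(31)
  incs <- unlist(lapply(1:400, function(i) {
    diff(generateCommonSurface(g, 12,
      hyper = list(alpha0 = 0, sigma2V = 0, sigma2Eta = 0,
                   sigma2Gamma = 0.05))$gamma)
  }))
  expect_equal(var(incs), 0.05, tolerance = 0.15)

  # ICAR draw of v: E[quadform] = sigma2V * rank(L)
  set.seed(32)
  quads <- sapply(1:400, function(i) {
    icarQuadform(generateCommonSurface(g, 2,
      hyper = list(alpha0 = 0, sigma2V = 0.1, sigma2Eta = 0,
                   sigma2Gamma = 0))$v, g)
  })
  expect_equal(mean(quads), 0.1 * (16 - 1), tolerance = 0.15)
})

test_that("unusual-area selection respects the spatial patterns", {
  p5 <- temporalPathGraph(5)  # path graph doubles as a 5-area geography
  set.seed(33)
  # the only independent set of size 3 on a path of 5
  expect_identical(selectUnusualAreas(p5, 3, "isolated"), c(1L, 3L, 5L))
  expect_error(selectUnusualAreas(p5, 4, "isolated", maxTries = 20),
               "non-adjacent")

  g <- latticeGraph(6, 6)
  adj <- adjacencyList(g)
  for (rep in 1:10) {
    iso <- selectUnusualAreas(g, 6, "isolated")
    for (i in iso) expect_false(any(adj[[i]] %in% setdiff(iso, i)))
  }

  # clusters are internally connected and pairwise non-adjacent
  for (rep in 1:10) {
    cl <- selectUnusualAreas(g, 15, "clustered")
    expect_identical(length(cl), 15L)
    sub <- neighborGraph(36, edgeMatrix(g))
    # components of the induced subgraph on cl
    keep <- edgeMatrix(g)[edgeMatrix(g)[, 1] %in% cl &
                          edgeMatrix(g)[, 2] %in% cl, , drop = FALSE]
    relab <- match(keep, cl); dim(relab) <- dim(keep)
    gi <- neighborGraph(15, relab)
    sizes <- table(componentLabels(gi))
    expect_identical(sort(as.integer(sizes)), c(5L, 5L, 5L))
  }

  # stratified selection spreads areas across size tertiles
  set.seed(34)
  strata <- seq_len(36)
  iso <- selectUnusualAreas(g, 6, "isolated", strata = strata)
  tert <- cut(rank(strata), 3, labels = FALSE)
  expect_identical(as.integer(table(tert[iso])), c(2L, 2L, 2L))
})

test_that("unusual temporal trends follow their construction rules", {
  set.seed(35)
  tr <- makeUnusualTrend("consecutive_stable", 15, 0.4)
  expect_identical(length(tr$affected), 5L)  # ceiling(15/3)
  expect_equal(unique(tr$departure[tr$affected]), 0.4)
  expect_equal(tr$departure[-tr$affected], rep(0, 10))
  expect_identical(tr$affected, seq(min(tr$affected), max(tr$affected)))

  for (rep in 1:20) {
    iso <- makeUnusualTrend("isolated", 10, 0.4)
    expect_true(all(diff(iso$affected) > 1))
    expect_true(all(abs(iso$departure[iso$affected]) == 0.4))
  }

  cv <- makeUnusualTrend("consecutive_variable", 15, 0.4)
  expect_true(all(abs(diff(sign(cv$departure[cv$affected]))) == 2))

  z <- makeUnusualTrend("consecutive_stable", 12, 0)
  expect_equal(z$departure, rep(0, 12))
  expect_identical(length(z$affected), 4L)  # truth still reported
  expect_error(makeUnusualTrend("isolated", 3, 0.4), "at least 4")
})

test_that("simulated scenarios carry consistent ground truth", {
  g <- latticeGraph(5, 5)
  spec <- scenarioSpec("S2", nUnusualAreas = 4, seed = 36)
  sim <- simulateScenario(spec, g)
  z <- trueAllocation(sim)
  expect_identical(sum(z == 0),
                   length(unlist(sim@unusualTimes)))
  expect_identical(sort(unique(which(rowSums(z == 0) > 0))),
                   as.integer(unusualAreas(sim)))
  expect_identical(sim@scenario, unclass(spec))

  s10 <- simulateScenario(scenarioSpec("S10", seed = 36), g)
  expect_true(all(trueAllocation(s10) == 1))
  expect_identical(length(unusualAreas(s10)), 0L)

  # determinism: identical spec gives an identical dataset
  sim2 <- simulateScenario(spec, g)
  expect_identical(counts(sim), counts(sim2))
  expect_identical(trueAllocation(sim), trueAllocation(sim2))
})

test_that("mean simulated SIR converges to the injected risk surface", {
  g <- latticeGraph(5, 5)
  hyper <- list(alpha0 = 0.3, sigma2V = 0, sigma2Eta = 0, sigma2Gamma = 0)
  spec <- scenarioSpec("S3", nUnusualAreas = 3, seed = 37, nSims = 200,
                       T = 15)
  sims <- batchSimulate(spec, g, hyper = hyper)
  # flat surface: every non-injected cell has mu = exp(0.3); injected
  # consecutive-stable cells have mu = exp(0.3 + 0.4)
  ratios <- sapply(sims, function(s) {
    r <- counts(s) / expectedCounts(s)
    c(common = mean(r[trueAllocation(s) == 1]),
      unusual = mean(r[trueAllocation(s) == 0]))
  })
  expect_equal(mean(ratios["common", ]), exp(0.3), tolerance = 0.02)
  expect_equal(mean(ratios["unusual", ]), exp(0.7), tolerance = 0.02)
})

test_that("batch simulation is reproducible with distinct replicates", {
  g <- latticeGraph(3, 3)
  spec <- scenarioSpec("S1", nUnusualAreas = 2, seed = 38, nSims = 4, T = 8)
  b1 <- batchSimulate(spec, g)
  b2 <- batchSimulate(spec, g)
  expect_identical(length(b1), 4L)
  for (r in 1:4) expect_identical(counts(b1[[r]]), counts(b2[[r]]))
  expect_false(identical(counts(b1[[1]]), counts(b1[[2]])))
})
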