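test_that("component linear predictors are elementwise sums", {
  p <- list(alpha0 = 1, eta = c(1, -1), gamma = c(0.5, -0.5))
  expect_equal(commonLinpred(p), rbind(c(2.5, 1.5), c(0.5, -0.5)))
  p0 <- list(alpha0 = 0, eta = rep(0, 3), gamma = rep(0, 4))
  expect_equal(commonLinpred(p0), matrix(0, 3, 4))
  p$alpha0 <- p$alpha0 + 2
  expect_equal(commonLinpred(p), rbind(c(2.5, 1.5), c(0.5, -0.5)) + 2)

  a <- list(nu = c(1, 2), kappa = rbind(c(0.1, -0.1), c(0, 0)))
  expect_equal(areaSpecificLinpred(a), rbind(c(1.1, 0.9), c(2, 2)))
  expect_equal(areaSpecificLinpred(list(nu = c(1, 2), kappa = matrix(0, 2, 3))),
               matrix(c(1, 2), 2, 3))
})

test_that("mixtureLinpred selects per cell and broadcasts per-area z", {
  set.seed(1)
  muC <- matrix(rnorm(12), 3, 4)
  muAS <- matrix(rnorm(12), 3, 4)
  expect_equal(mixtureLinpred(matrix(1, 3, 4), muC, muAS), muC)
  expect_equal(mixtureLinpred(matrix(0, 3, 4), muC, muAS), muAS)

  z <- matrix(rbinom(12, 1, 0.5), 3, 4)
  out <- mixtureLinpred(z, muC, muAS)
  for (i in 1:3) for (t in 1:4) {
    expect_identical(out[i, t], if (z[i, t] == 1) muC[i, t] else muAS[i, t])
  }

  # per-area vector equals the matrix with rows replicated across time
  zi <- c(1, 0, 1)
  expect_equal(mixtureLinpred(zi, muC, muAS),
               mixtureLinpred(matrix(zi, 3, 4), muC, muAS))
  expect_error(mixtureLinpred(matrix(0.5, 3, 4), muC, muAS), "binary")
})

test_that("poissonLogLik matches the closed-form Poisson log-pmf", {
  d <- list(Y = matrix(0, 2, 3), E = matrix(2, 2, 3))
  expect_equal(poissonLogLik(d, matrix(0, 2, 3)), -sum(d$E))

  d1 <- list(Y = matrix(2), E = matrix(1))
  expect_equal(poissonLogLik(d1, matrix(0)), -1 - log(2))

  set.seed(2)
  Y <- matrix(rpois(12, 5), 3, 4)
  E <- matrix(runif(12, 0.5, 2), 3, 4)
  logMu <- matrix(rnorm(12, 0, 0.3), 3, 4)
  manual <- sum(Y * (log(E) + logMu) - E * exp(logMu) - lfactorial(Y))
  expect_equal(poissonLogLik(list(Y = Y, E = E), logMu), manual,
               tolerance = 1e-10)

  # maximised cellwise at logMu = log(Y/E) (all Y > 0 here)
  Y1 <- Y + 1
  atMle <- poissonLogLik(list(Y = Y1, E = E), log(Y1 / E))
  expect_true(atMle > poissonLogLik(list(Y = Y1, E = E), log(Y1 / E) + 0.1))
  expect_error(poissonLogLik(list(Y = Y, E = -E), logMu), "positive")
})

test_that("phiField is the logistic of pi + delta + logit(tau)", {
  expect_equal(phiField(rep(0, 3), rep(0, 4), 0.95), matrix(0.95, 3, 4))
  expect_equal(phiField(c(1, -1), 0, 0.5)[, 1], plogis(c(1, -1)))
  expect_true(phiField(50, 0, 0.5)[1, 1] > 1 - 1e-10)
  expect_error(phiField(0, 0, 1), "inside")
  expect_error(phiField(0, 0, 0), "inside")
})

# a random parameter state inside both priors' support
randomState <- function(N, T) {
  list(alpha0 = rnorm(1), eta = rnorm(N), v = rnorm(N), gamma = rnorm(T),
       sigma2Eta = runif(1, 0.05, 1), sigma2V = runif(1, 0.05, 1),
       sigma2Gamma = runif(1, 0.05, 1), nu = rnorm(N),
       kappa = matrix(rnorm(N * T), N, T),
       sigma2Kappa = runif(N, 0.05, 1), a = rnorm(1), b = runif(1, 0.5, 2),
       z = rbinom(N, 1, 0.5), pi = rnorm(N), delta = rnorm(T),
       tau = runif(1, 0.91, 0.99),
       sigma2Pi = runif(1, 0.05, 1), sigma2Delta = runif(1, 0.05, 1))
}

test_that("baseline prior assembles its component densities", {
  set.seed(3)
  N <- 5; T <- 4
  W <- randomGraph(N, 0.5); Q <- temporalPathGraph(T)
  s <- randomState(N, T)

  s1 <- s; s1$z <- rep(1, N)
  s0 <- s; s0$z <- rep(0, N)
  expect_equal(logPriorBaseline(s1, W, Q) - logPriorBaseline(s0, W, Q),
               N * (log(0.95) - log(0.05)))

  # independent term-by-term evaluation
  manual <- icarLogpdf(s$v, W, s$sigma2V) +
    sum(dnorm(s$eta, s$v, sqrt(s$sigma2Eta), log = TRUE)) +
    icarLogpdf(s$gamma, Q, s$sigma2Gamma) +
    sum(dnorm(s$nu, 0, sqrt(1000), log = TRUE)) +
    sum(sapply(1:N, function(i) icarLogpdf(s$kappa[i, ], Q, s$sigma2Kappa[i]))) +
    sum(dlnorm(s$sigma2Kappa, s$a, s$b, log = TRUE)) +
    dnorm(s$a, 0, sqrt(1000), log = TRUE) +
    dnorm(s$b, 0, 2.5, log = TRUE) + log(2) +
    sum(dnorm(c(s$sigma2Eta, s$sigma2V, s$sigma2Gamma), 0, 1, log = TRUE) + log(2)) +
    sum(s$z * log(0.95) + (1 - s$z) * log(0.05))
  expect_equal(logPriorBaseline(s, W, Q), manual)
  expect_true(is.finite(logPriorBaseline(s, W, Q)))

  sBad <- s; sBad$sigma2V <- -1
  expect_identical(logPriorBaseline(sBad, W, Q), -Inf)
})

test_that("proposed prior uses the hierarchical allocation field", {
  set.seed(4)
  N <- 5; T <- 4
  W <- randomGraph(N, 0.5); Q <- temporalPathGraph(T)
  s <- randomState(N, T)
  s$z <- matrix(rbinom(N * T, 1, 0.5), N, T)

  sBad <- s; sBad$tau <- 0.85
  expect_identical(logPriorProposed(sBad, W, Q), -Inf)

  # with flat allocation fields the Bernoulli block reduces to
  # counts of ones and zeros at tau
  sFlat <- s; sFlat$pi <- rep(0, N); sFlat$delta <- rep(0, T)
  sFlat1 <- sFlat; sFlat1$z <- matrix(1, N, T)
  sFlat0 <- sFlat; sFlat0$z <- matrix(0, N, T)
  expect_equal(logPriorProposed(sFlat1, W, Q) - logPriorProposed(sFlat0, W, Q),
               N * T * (log(sFlat$tau) - log(1 - sFlat$tau)))

  # Bernoulli block matches a brute-force loop
  phi <- phiField(s$pi, s$delta, s$tau)
  bern <- 0
  for (i in 1:N) for (t in 1:T) {
    bern <- bern + s$z[i, t] * log(phi[i, t]) +
      (1 - s$z[i, t]) * log(1 - phi[i, t])
  }
  sNoZ1 <- s; sNoZ1$z <- matrix(1, N, T)
  bern1 <- sum(log(phi))
  expect_equal(logPriorProposed(s, W, Q) - logPriorProposed(sNoZ1, W, Q),
               bern - bern1)
})
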