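#' MCMC configuration
#'
#' Defaults follow the production run settings used for a full-scale
#' analysis: two chains of 80 000 iterations with every second draw stored
#' and the first 20 000 discarded as burn-in. For simulation studies and
#' examples, much shorter runs are appropriate (see the methods vignette).
#'
#' @param nIter total iterations per chain.
#' @param burnIn iterations discarded (must be < `nIter`).
#' @param thin storage interval for monitored traces (>= 1).
#' @param nChains number of independent chains.
#' @param seed integer RNG seed; chain c uses `seed + c - 1`.
#' @param adapt tune the random-walk step sizes during burn-in toward an
#'   acceptance rate of 0.44.
#' @return A validated list of class `mcmcConfig`.
#' @export
mcmcConfig <- function(nIter = 80000L, burnIn = 20000L, thin = 2L,
                       nChains = 2L, seed = 1L, adapt = TRUE) {
  nIter <- as.integer(nIter); burnIn <- as.integer(burnIn)
  thin <- as.integer(thin); nChains <- as.integer(nChains)
  if (burnIn < 0L || burnIn >= nIter) stop("'burnIn' must satisfy 0 <= burnIn < nIter")
  if (thin < 1L) stop("'thin' must be >= 1")
  if (nChains < 1L) stop("'nChains' must be >= 1")
  structure(list(nIter = nIter, burnIn = burnIn, thin = thin,
                 nChains = nChains, seed = as.integer(seed), adapt = adapt),
            class = "mcmcConfig")
}

#' Read an MCMC configuration from a DCF text file
#'
#' Reads `key: value` lines (Debian-control format) with any subset of the
#' [mcmcConfig()] fields (`nIter`, `burnIn`, `thin`, `nChains`, `seed`,
#' `adapt`); unspecified fields keep their defaults.
#'
#' @param path file path.
#' @return A validated `mcmcConfig` list.
#' @export
readMCMCConfig <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- names(formals(mcmcConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$adapt)) raw$adapt <- as.logical(raw$adapt)
  do.call(mcmcConfig, lapply(raw, function(x) utils::type.convert(x, as.is = TRUE)))
}

#' Full conditional of an allocation indicator
#'
#' Posterior probability that a unit (an area for the baseline model, an
#' area-time cell for the proposed one) is allocated to the Common component:
#' `p = prior * exp(LC) / (prior * exp(LC) + (1 - prior) * exp(LAS))`,
#' evaluated stably on the log scale. `LC` and `LAS` are the data
#' log-likelihoods of the unit under the Common and Area-Specific components
#' at the current parameter values; `prior` is the prior allocation
#' probability (0.95 for the baseline model, `phi[i, t]` for the proposed).
#'
#' @param loglikC,loglikAS log-likelihoods under each component (vectorised).
#' @param priorProb prior probability of the Common component, in (0, 1).
#' @return Probability (or vector of probabilities) in \[0, 1\].
#' @export
zFullConditional <- function(loglikC, loglikAS, priorProb) {
  if (any(priorProb <= 0 | priorProb >= 1)) {
    stop("'priorProb' must lie strictly inside (0, 1)")
  }
  # p = plogis(logit(prior) + LC - LAS); -Inf log-likelihoods are allowed
  d <- stats::qlogis(priorProb) + loglikC - loglikAS
  d[loglikC == -Inf & loglikAS == -Inf] <- NA_real_
  stats::plogis(d)
}

#' Fit a surveillance mixture model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler for the baseline model (per-area
#' allocation with a Bernoulli(0.95) prior and FDR-based detection) or the
#' proposed model (per-cell allocation with a hierarchical spatio-temporal
#' prior). One sweep updates, in order: the Common-model block (intercept,
#' BYM spatial field with a conjugate update for the structured part,
#' national RW1 trend), the Area-Specific block (intercepts, per-area RW1
#' trends), all variance hyperparameters, the allocation field z from its
#' exact full conditional, and, for the proposed model, the allocation-prior
#' fields pi, delta and the level tau. Both model components are fitted to
#' the full data and z carries no feedback into the component fits (the cut
#' factorization of the original method; see the methods vignette). ICAR
#' fields are recentred every sweep. Runs are reproducible given
#' `config$seed`.
#'
#' @param data a [SurveillanceCounts-class] object.
#' @param graph spatial [NeighborGraph-class] over the areas.
#' @param model `"baseline"` or `"proposed"`.
#' @param config an [mcmcConfig()] list.
#' @return A [PosteriorSamples-class] object; `allocationProb()` extracts the
#'   posterior allocation probabilities f (averaged over chains).
#' @examples
#' g <- latticeGraph(3, 3)
#' sim <- simulateScenario(scenarioSpec("S10", seed = 1), g)
#' fit <- runMCMC(sim, g, "proposed",
#'                mcmcConfig(nIter = 200, burnIn = 100, nChains = 1))
#' summary(allocationProb(fit))
#' @export
runMCMC <- function(data, graph, model = c("proposed", "baseline"),
                    config = mcmcConfig()) {
  model <- match.arg(model)
  stopifnot(is(data, "SurveillanceCounts"), is(graph, "NeighborGraph"))
  Y <- counts(data); E <- expectedCounts(data)
  if (nrow(Y) != nNodes(graph)) {
    stop("the spatial graph must have one node per area")
  }
  if (ncol(Y) < 2L) stop("at least two time points are required")
  modelCode <- if (model == "proposed") 1L else 0L

  fSum <- 0
  chains <- vector("list", config$nChains)
  rates <- NULL
  pm <- NULL
  for (ch in seq_len(config$nChains)) {
    set.seed(config$seed + ch - 1L)
    res <- cpp_run_sampler(modelCode, Y, E, adjacencyList(graph),
                           componentLabels(graph),
                           config$nIter, config$burnIn, config$thin,
                           config$adapt, 0.95, TRUE)
    if (any(!is.finite(res$f))) {
      stop("non-finite allocation probabilities: the sampler failed to ",
           "initialise; check that counts and expected values are valid")
    }
    fSum <- fSum + res$f
    keep <- if (model == "proposed") {
      c("alpha0", "gamma", "sigma2Eta", "sigma2V", "sigma2Gamma",
        "tau", "sigma2Pi", "sigma2Delta")
    } else {
      c("alpha0", "gamma", "sigma2Eta", "sigma2V", "sigma2Gamma", "a", "b")
    }
    chains[[ch]] <- res$traces[keep]
    if (is.null(rates)) rates <- res$acceptanceRates
    pm <- res[c("etaMean", "gammaMean", "nuMean", "kappaMean")]
  }
  f <- fSum / config$nChains
  dimnames(f) <- dimnames(Y)
  if (model == "baseline") f <- f[, 1L]   # z constant across time by design
  if (model == "baseline") {
    rates <- rates[setdiff(names(rates),
                           c("pi", "delta", "tau", "sigma2Pi", "sigma2Delta"))]
  } else {
    rates <- rates[setdiff(names(rates), "b")]
  }
  new("PosteriorSamples",
      model = model, f = f, draws = chains,
      posteriorMeans = list(eta = pm$etaMean, gamma = pm$gammaMean,
                            nu = pm$nuMean, kappa = pm$kappaMean),
      acceptanceRates = rates,
      config = unclass(config), dims = c(nrow(Y), ncol(Y)))
}

#' @rdname allocationProb
#' @export
setMethod("allocationProb", "PosteriorSamples", function(x) x@f)

setMethod("show", "PosteriorSamples", function(object) {
  cfg <- object@config
  cat("PosteriorSamples:", object@model, "model,",
      cfg$nChains, "chain(s) x", cfg$nIter, "iterations (burn-in",
      paste0(cfg$burnIn, ")"), "\n")
  cat("  areas:", object@dims[1L], " time points:", object@dims[2L], "\n")
  f <- as.numeric(object@f)
  cat("  allocation probabilities f: mean", round(mean(f), 3),
      " min", round(min(f), 3), "\n")
  r <- object@acceptanceRates
  r <- r[!is.na(r)]
  cat("  Metropolis acceptance rates:",
      paste0(names(r), "=", round(r, 2), collapse = " "), "\n")
})

#' Potential scale reduction factor (Gelman-Rubin / Brooks-Gelman-Rubin)
#'
#' Convergence diagnostic comparing between-chain and within-chain variance
#' of a scalar parameter; values near 1 indicate the chains are sampling the
#' same distribution.
#'
#' @param chains matrix with one column per chain (rows = stored iterations),
#'   or a list of equal-length numeric vectors.
#' @return Scalar PSRF estimate (approximately >= 1).
#' @export
gelmanRubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2L) stop("at least two chains are required")
  if (n < 2L) stop("chains must have length >= 2")
  means <- colMeans(chains)
  B <- n * var(means)
  W <- mean(apply(chains, 2L, var))
  if (W == 0) return(1)
  varPlus <- (n - 1) / n * W + B / n
  sqrt(varPlus / W)
}

#' Monte Carlo standard error by batch means
#'
#' Splits a chain into consecutive batches and estimates the standard error
#' of the posterior-mean estimate from the batch means, accounting for
#' autocorrelation at lags shorter than the batch length.
#'
#' @param draws numeric vector of MCMC draws.
#' @param batches number of batches (>= 2); trailing draws that do not fill
#'   a complete batch are dropped.
#' @return Non-negative scalar standard error.
#' @export
mcError <- function(draws, batches = 20L) {
  batches <- as.integer(batches)
  if (batches < 2L) stop("'batches' must be >= 2")
  b <- length(draws) %/% batches
  if (b < 1L) stop("too few draws for the requested number of batches")
  m <- colMeans(matrix(draws[seq_len(b * batches)], nrow = b))
  sd(m) / sqrt(batches)
}
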