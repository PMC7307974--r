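#' Scenario specification for the synthetic surveillance generator
#'
#' The ten study scenarios cross a spatial pattern for the injected unusual
#' areas (isolated: pairwise non-adjacent; clustered: connected groups), a
#' temporal pattern for the injected departures (isolated spikes,
#' consecutive-variable, consecutive-stable), the series length (S7 uses 30
#' time points instead of 15), the magnitude of the expected counts (S8
#' doubled, S9 halved) and a no-aberration null (S10).
#'
#' @param id scenario id, `"S1"` to `"S10"`. Supplying an id fills in the
#'   scenario's canonical pattern, length and scale; the remaining arguments
#'   override the generator defaults.
#' @param T number of time points.
#' @param nUnusualAreas number of injected unusual areas (default 15;
#'   forced to 0 for S10).
#' @param expectedScale multiplier applied to the baseline expected counts.
#' @param nSims number of replicate datasets for [batchSimulate()]
#'   (default 50).
#' @param seed integer seed.
#' @param departureMagnitude size of the injected log-risk departures
#'   (default 0.4).
#' @param spatialPattern,temporalPattern override the scenario's patterns.
#' @return A list of class `scenarioSpec`.
#' @export
scenarioSpec <- function(id = c("S1", "S2", "S3", "S4", "S5", "S6", "S7",
                                "S8", "S9", "S10"),
                         T = NULL, nUnusualAreas = 15L, expectedScale = NULL,
                         nSims = 50L, seed = 1L, departureMagnitude = 0.4,
                         spatialPattern = NULL, temporalPattern = NULL) {
  id <- match.arg(id)
  tab <- list(
    S1 = c("isolated", "isolated"),
    S2 = c("isolated", "consecutive_variable"),
    S3 = c("isolated", "consecutive_stable"),
    S4 = c("clustered", "isolated"),
    S5 = c("clustered", "consecutive_variable"),
    S6 = c("clustered", "consecutive_stable"),
    S7 = c("isolated", "consecutive_variable"),
    S8 = c("isolated", "consecutive_variable"),
    S9 = c("isolated", "consecutive_variable"),
    S10 = c("none", "none"))
  sp <- spatialPattern %||% tab[[id]][1L]
  tp <- temporalPattern %||% tab[[id]][2L]
  if (is.null(T)) T <- if (id == "S7") 30L else 15L
  if (is.null(expectedScale)) {
    expectedScale <- switch(id, S8 = 2, S9 = 0.5, 1)
  }
  if (id == "S10") nUnusualAreas <- 0L
  if (expectedScale <= 0) stop("'expectedScale' must be positive")
  structure(list(id = id, spatialPattern = sp, temporalPattern = tp,
                 T = as.integer(T), nUnusualAreas = as.integer(nUnusualAreas),
                 expectedScale = expectedScale, nSims = as.integer(nSims),
                 seed = as.integer(seed),
                 departureMagnitude = departureMagnitude),
            class = "scenarioSpec")
}

#' Draw a Common-model risk surface
#'
#' Samples the background (normal-conditions) log relative risk surface:
#' the structured spatial field `v` from the sum-to-zero-constrained ICAR on
#' the area graph (via the spectral decomposition of its graph Laplacian),
#' the convolved field `eta ~ Normal(v, sigma2Eta)`, and the national trend
#' `gamma` as a recentred first-order random walk.
#'
#' @param graph spatial [NeighborGraph-class].
#' @param T number of time points (>= 2).
#' @param hyper list of surface hypervalues: `alpha0`, `sigma2V`,
#'   `sigma2Eta`, `sigma2Gamma`. The defaults are synthetic stand-ins for
#'   posterior estimates from a real application (see the methods vignette);
#'   substitute your own when emulating specific data.
#' @return List with elements `alpha0`, `eta`, `v`, `gamma` and the
#'   hypervalues.
#' @export
generateCommonSurface <- function(graph, T,
                                  hyper = list(alpha0 = 0, sigma2V = 0.1,
                                               sigma2Eta = 0.01,
                                               sigma2Gamma = 0.05)) {
  stopifnot(is(graph, "NeighborGraph"), T >= 2)
  N <- nNodes(graph)
  v <- if (hyper$sigma2V > 0) .ricar(graph, hyper$sigma2V) else numeric(N)
  eta <- v + rnorm(N, 0, sqrt(hyper$sigma2Eta))
  gamma <- if (hyper$sigma2Gamma > 0) {
    g <- cumsum(c(0, rnorm(T - 1L, 0, sqrt(hyper$sigma2Gamma))))
    g - mean(g)
  } else numeric(T)
  c(list(alpha0 = hyper$alpha0, v = v, eta = eta, gamma = gamma), hyper)
}

# exact draw from the sum-to-zero-constrained ICAR via the eigendecomposition
# of the graph Laplacian D - W; null-space directions (one per component)
# are dropped
.ricar <- function(graph, sigma2) {
  N <- nNodes(graph)
  L <- diag(as.numeric(neighborCounts(graph)), N, N)
  e <- edgeMatrix(graph)
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      L[e[k, 1L], e[k, 2L]] <- L[e[k, 1L], e[k, 2L]] - 1
      L[e[k, 2L], e[k, 1L]] <- L[e[k, 2L], e[k, 1L]] - 1
    }
  }
  ev <- eigen(L, symmetric = TRUE)
  pos <- ev$values > 1e-8 * max(ev$values, 1)
  if (!any(pos)) return(numeric(N))
  coef <- rnorm(sum(pos), 0, sqrt(sigma2 / ev$values[pos]))
  as.numeric(ev$vectors[, pos, drop = FALSE] %*% coef)
}

#' Select the injected unusual areas
#'
#' `pattern = "isolated"` draws a set of pairwise non-adjacent areas;
#' `pattern = "clustered"` grows connected clusters (by default as close to
#' 3 equal clusters as `n` allows; 3 clusters of 5 for the default n = 15)
#' that do not touch each other. Optionally the isolated selection is
#' stratified across tertiles of a per-area size variable (e.g. expected
#' counts), spreading the injected areas over small, medium and large areas.
#'
#' @param graph spatial [NeighborGraph-class].
#' @param n number of areas to select.
#' @param pattern `"isolated"` or `"clustered"`.
#' @param strata optional numeric per-area variable whose tertiles stratify
#'   the isolated selection.
#' @param nClusters number of clusters for the clustered pattern.
#' @param maxTries attempts before declaring the pattern infeasible.
#' @return Sorted integer vector of area indices.
#' @export
selectUnusualAreas <- function(graph, n, pattern = c("isolated", "clustered"),
                               strata = NULL, nClusters = 3L,
                               maxTries = 200L) {
  pattern <- match.arg(pattern)
  N <- nNodes(graph)
  if (n > N) stop("cannot select more unusual areas than areas")
  adj <- adjacencyList(graph)
  if (pattern == "isolated") {
    quota <- NULL
    if (!is.null(strata)) {
      tert <- cut(rank(strata, ties.method = "first"), 3L, labels = FALSE)
      quota <- tabulate(rep_len(seq_len(3L), n), nbins = 3L)
    }
    for (try in seq_len(maxTries)) {
      chosen <- integer()
      taken <- tabulate(integer(), nbins = 3L)
      for (i in sample.int(N)) {
        if (length(chosen) == n) break
        if (any(adj[[i]] %in% chosen)) next
        if (!is.null(quota) && taken[tert[i]] >= quota[tert[i]]) next
        chosen <- c(chosen, i)
        if (!is.null(quota)) taken[tert[i]] <- taken[tert[i]] + 1L
      }
      if (length(chosen) == n) return(sort(chosen))
    }
    stop("could not find ", n, " pairwise non-adjacent areas on this graph")
  }
  # clustered: near-equal split of n over the clusters
  sizes <- rep(n %/% nClusters, nClusters)
  extra <- n %% nClusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes <- sizes[sizes > 0L]
  for (try in seq_len(maxTries)) {
    used <- integer(); blocked <- integer(); ok <- TRUE
    for (s in sizes) {
      avail <- setdiff(seq_len(N), union(used, blocked))
      if (!length(avail)) { ok <- FALSE; break }
      seed <- if (length(avail) == 1L) avail else sample(avail, 1L)
      clus <- seed
      while (length(clus) < s) {
        frontier <- setdiff(unique(unlist(adj[clus])), union(clus, union(used, blocked)))
        if (!length(frontier)) break
        clus <- c(clus, if (length(frontier) == 1L) frontier else sample(frontier, 1L))
      }
      if (length(clus) < s) { ok <- FALSE; break }
      used <- c(used, clus)
      blocked <- union(blocked, unlist(adj[clus]))  # keep clusters apart
    }
    if (ok) return(sort(used))
  }
  stop("could not place ", length(sizes), " disjoint clusters of sizes ",
       paste(sizes, collapse = "/"), " on this graph")
}

#' Construct an unusual temporal departure
#'
#' Builds the log-scale departure added to an unusual area's risk:
#' `"isolated"` places `nSpikes` departures of size `+-magnitude` at
#' non-adjacent time points; `"consecutive_variable"` fills a contiguous
#' window of length `ceiling(T/3)` with alternating-sign departures;
#' `"consecutive_stable"` fills the same window with a constant
#' `+magnitude`. Unaffected times are 0. The affected-time set is returned
#' as ground truth (also when `magnitude = 0`, for power-versus-magnitude
#' curves).
#'
#' @param pattern one of `"isolated"`, `"consecutive_variable"`,
#'   `"consecutive_stable"`.
#' @param T number of time points (>= 4).
#' @param magnitude departure size on the log-risk scale (>= 0).
#' @param nSpikes number of isolated spikes (default 2).
#' @return List with `departure` (length-T numeric) and `affected`
#'   (integer time indices).
#' @export
makeUnusualTrend <- function(pattern = c("isolated", "consecutive_variable",
                                         "consecutive_stable"),
                             T, magnitude, nSpikes = 2L) {
  pattern <- match.arg(pattern)
  T <- as.integer(T)
  if (T < 4L) stop("'T' must be at least 4")
  dep <- numeric(T)
  if (pattern == "isolated") {
    repeat {
      at <- sort(sample.int(T, nSpikes))
      if (nSpikes < 2L || all(diff(at) > 1L)) break
    }
    dep[at] <- magnitude * sample(c(-1, 1), nSpikes, replace = TRUE)
    affected <- at
  } else {
    len <- ceiling(T / 3)
    if (len > T) stop("'T' too short for the departure window")
    start <- sample.int(T - len + 1L, 1L)
    affected <- seq.int(start, start + len - 1L)
    if (pattern == "consecutive_variable") {
      signs <- rep_len(c(1, -1), len) * sample(c(-1, 1), 1L)
      dep[affected] <- magnitude * signs
    } else {
      dep[affected] <- magnitude
    }
  }
  list(departure = dep, affected = affected)
}

#' Baseline expected counts
#'
#' Per-area expected counts (constant over time), drawn lognormal around
#' `meanE` to span roughly an order of magnitude across areas.
#'
#' @param N number of areas (or a [NeighborGraph-class]).
#' @param T number of time points.
#' @param meanE mean expected count per area-time cell (default 100).
#' @param sdlog lognormal spread (default 0.5).
#' @return N-by-T positive matrix.
#' @export
defaultExpected <- function(N, T, meanE = 100, sdlog = 0.5) {
  if (is(N, "NeighborGraph")) N <- nNodes(N)
  e <- stats::rlnorm(N, log(meanE) - sdlog^2 / 2, sdlog)
  matrix(e, N, T)
}

#' Simulate one scenario dataset
#'
#' Draws a Common-model surface, injects the scenario's unusual temporal
#' departures into the selected areas, and samples
#' `Y[i, t] ~ Poisson(mu[i, t] * E[i, t])` with
#' `E = expectedScale * EBase`. The ground-truth allocation matrix has zeros
#' exactly at the injected (area, affected-time) cells; the no-aberration
#' scenario injects nothing.
#'
#' @param spec a [scenarioSpec()].
#' @param graph spatial [NeighborGraph-class].
#' @param EBase N-by-T positive matrix of baseline expected counts; by
#'   default drawn with [defaultExpected()].
#' @param hyper Common-surface hypervalues, see [generateCommonSurface()].
#' @param stratify stratify the isolated-area selection across expected-count
#'   tertiles.
#' @return A [SimulatedCounts-class] object.
#' @examples
#' g <- latticeGraph(5, 5)
#' sim <- simulateScenario(scenarioSpec("S2", nUnusualAreas = 3, seed = 7), g)
#' length(unusualAreas(sim))
#' @export
simulateScenario <- function(spec, graph, EBase = NULL, hyper = NULL,
                             stratify = FALSE) {
  stopifnot(inherits(spec, "scenarioSpec"), is(graph, "NeighborGraph"))
  set.seed(spec$seed)
  N <- nNodes(graph); T <- spec$T
  if (is.null(EBase)) EBase <- defaultExpected(N, T)
  if (!identical(dim(EBase), c(N, T))) {
    stop("'EBase' must be an N-by-T matrix matching the graph and spec")
  }
  if (any(EBase <= 0)) stop("'EBase' must be strictly positive")
  E <- spec$expectedScale * EBase
  surf <- if (is.null(hyper)) generateCommonSurface(graph, T) else
    generateCommonSurface(graph, T, hyper)
  logMu <- commonLinpred(surf)

  zTrue <- matrix(1, N, T)
  areas <- integer(); times <- list()
  if (spec$nUnusualAreas > 0L) {
    areas <- selectUnusualAreas(
      graph, spec$nUnusualAreas, spec$spatialPattern,
      strata = if (stratify) EBase[, 1L] else NULL)
    times <- vector("list", length(areas))
    for (k in seq_along(areas)) {
      tr <- makeUnusualTrend(spec$temporalPattern, T, spec$departureMagnitude)
      logMu[areas[k], ] <- logMu[areas[k], ] + tr$departure
      zTrue[areas[k], tr$affected] <- 0
      times[[k]] <- tr$affected
    }
  }
  Y <- matrix(rpois(N * T, E * exp(logMu)), N, T)
  sc <- surveillanceCounts(Y, E)
  new("SimulatedCounts", sc, zTrue = zTrue, unusualAreas = areas,
      unusualTimes = times, generatorParams = surf,
      scenario = unclass(spec))
}

#' Simulate a batch of replicate datasets
#'
#' Generates `spec$nSims` independent datasets; replicate r uses seed
#' `spec$seed + r`, so a batch is reproducible from the spec alone and any
#' replicate can be regenerated individually.
#'
#' @inheritParams simulateScenario
#' @return List of [SimulatedCounts-class] objects.
#' @export
batchSimulate <- function(spec, graph, EBase = NULL, hyper = NULL,
                          stratify = FALSE) {
  lapply(seq_len(spec$nSims), function(r) {
    s <- spec
    s$seed <- spec$seed + r
    simulateScenario(s, graph, EBase = EBase, hyper = hyper,
                     stratify = stratify)
  })
}
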