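#' Undirected neighbourhood graph for ICAR-type priors
#'
#' Stores the binary spatial adjacency W (areas sharing a border) or its
#' temporal analogue Q (time points at lag one), as an undirected simple
#' graph: no self loops, symmetric by construction, duplicate edges collapsed.
#' Nodes with no neighbours (islands) are permitted; each forms its own
#' connected component and contributes nothing to the ICAR quadratic form.
#'
#' @slot nNodes number of nodes.
#' @slot edges two-column integer matrix of unordered pairs, 1-based, i < j.
#' @slot neighborCounts integer vector; entry i is the degree of node i.
#' @slot componentLabels integer vector of connected-component ids.
#' @slot adjacency list of integer vectors; element i holds node i's
#'   neighbours.
#'
#' @seealso [neighborGraph()], [latticeGraph()], [temporalPathGraph()],
#'   [readGAL()]
#' @export
setClass("NeighborGraph",
  representation(
    nNodes = "integer",
    edges = "matrix",
    neighborCounts = "integer",
    componentLabels = "integer",
    adjacency = "list"
  )
)

setValidity("NeighborGraph", function(object) {
  n <- object@nNodes
  e <- object@edges
  msg <- character()
  if (length(n) != 1L || is.na(n) || n < 1L) {
    msg <- c(msg, "nNodes must be a single positive integer")
  }
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge endpoints out of range")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "edges must be stored with i < j")
    if (anyDuplicated(e)) msg <- c(msg, "duplicate edges")
  }
  if (length(object@neighborCounts) != n) {
    msg <- c(msg, "neighborCounts length must equal nNodes")
  } else {
    deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
    if (!identical(as.integer(deg), object@neighborCounts)) {
      msg <- c(msg, "neighborCounts inconsistent with the edge list")
    }
  }
  if (length(object@componentLabels) != n) {
    msg <- c(msg, "componentLabels length must equal nNodes")
  }
  if (length(msg)) msg else TRUE
})

#' Area-by-time surveillance counts with exposure
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding two
#' assays over areas (rows) and time points (columns): `"counts"`, the
#' observed non-negative integer event counts Y, and `"expected"`, the
#' strictly positive exposure offset E (expected cases from standardisation,
#' or e.g. traffic volume). The Poisson mean of cell (i, t) is
#' `mu[i,t] * E[i,t]`, with `mu` the relative risk modelled on the log scale.
#'
#' @seealso [surveillanceCounts()], [readCountsCSV()]
#' @export
#' @import SummarizedExperiment
setClass("SurveillanceCounts", contains = "SummarizedExperiment")

setValidity("SurveillanceCounts", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "expected") %in% an)) {
    return("assays 'counts' and 'expected' are required")
  }
  Y <- SummarizedExperiment::assay(object, "counts")
  E <- SummarizedExperiment::assay(object, "expected")
  if (any(is.na(Y)) || any(Y < 0) || any(Y != round(Y))) {
    msg <- c(msg, "'counts' must be non-negative integers")
  }
  if (any(is.na(E)) || any(E <= 0)) {
    msg <- c(msg, "'expected' must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated surveillance dataset with known ground truth
#'
#' A [SurveillanceCounts-class] extension produced by the scenario generator:
#' counts drawn from the Common model surface with unusual temporal departures
#' injected into selected areas, together with the truth needed for
#' evaluation.
#'
#' @slot zTrue binary area-by-time matrix; 1 = Common-model cell, 0 = injected
#'   unusual cell.
#' @slot unusualAreas integer indices of the injected areas.
#' @slot unusualTimes list, one integer vector of affected time points per
#'   unusual area.
#' @slot generatorParams list snapshot of the Common-model surface used
#'   (alpha0, eta, v, gamma, variances).
#' @slot scenario list of scenario metadata (id, patterns, seed, ...).
#'
#' @seealso [simulateScenario()], [batchSimulate()]
#' @export
setClass("SimulatedCounts",
  contains = "SurveillanceCounts",
  representation(
    zTrue = "matrix",
    unusualAreas = "integer",
    unusualTimes = "list",
    generatorParams = "list",
    scenario = "list"
  )
)

setValidity("SimulatedCounts", function(object) {
  msg <- character()
  z <- object@zTrue
  if (!identical(dim(z), dim(object))) {
    msg <- c(msg, "zTrue dimensions must match the count matrix")
  }
  if (!all(z %in% c(0, 1))) msg <- c(msg, "zTrue must be binary")
  if (length(object@unusualTimes) != length(object@unusualAreas)) {
    msg <- c(msg, "unusualTimes must have one entry per unusual area")
  }
  inj <- matrix(1, nrow(z), ncol(z))
  if (length(object@unusualAreas)) {
    for (k in seq_along(object@unusualAreas)) {
      inj[object@unusualAreas[k], object@unusualTimes[[k]]] <- 0
    }
  }
  if (!all(z == inj)) {
    msg <- c(msg, "zTrue zeros must coincide exactly with the injected cells")
  }
  if (length(msg)) msg else TRUE
})

#' Posterior samples from the mixture-model MCMC
#'
#' Container returned by [runMCMC()]. Traces are stored only for the
#' monitored parameters (intercept, national trend, variance hyperparameters,
#' tau); the allocation field is accumulated online into its posterior mean
#' `f`, and the component surfaces into posterior-mean matrices.
#'
#' @slot model `"baseline"` or `"proposed"`.
#' @slot f posterior allocation probabilities: N-vector (baseline) or N-by-T
#'   matrix (proposed), entries in \[0, 1\].
#' @slot draws list, one element per chain; each a list of per-parameter trace
#'   arrays (rows = stored iterations).
#' @slot posteriorMeans list of posterior-mean summaries (eta, gamma, nu,
#'   kappa, commonLinpred, areaSpecificLinpred).
#' @slot acceptanceRates named numeric vector of post-burn-in Metropolis
#'   acceptance rates per update block.
#' @slot config the [mcmcConfig()] list used.
#' @slot dims c(N, T).
#'
#' @export
setClass("PosteriorSamples",
  representation(
    model = "character",
    f = "ANY",
    draws = "list",
    posteriorMeans = "list",
    acceptanceRates = "numeric",
    config = "list",
    dims = "integer"
  )
)

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  if (!object@model %in% c("baseline", "proposed")) {
    msg <- c(msg, "model must be 'baseline' or 'proposed'")
  }
  fv <- as.numeric(object@f)
  if (any(is.na(fv)) || any(fv < 0) || any(fv > 1)) {
    msg <- c(msg, "allocation probabilities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Detection result
#'
#' Declared-unusual flags produced by one of the two decision rules: the
#' Bayesian false discovery rate rule applied to per-area allocation
#' probabilities (baseline model) or the fixed probability threshold applied
#' per area-time cell (proposed model).
#'
#' @slot flags logical vector (per area) or matrix (per cell); `TRUE` =
#'   declared unusual.
#' @slot f the allocation probabilities the rule was applied to.
#' @slot thresholdUsed the realised cutoff C: the k-th smallest f under the
#'   FDR rule, or the fixed level.
#' @slot rule `"fdr"` or `"fixed"`.
#' @slot level the nominal level (FDR alpha, or the fixed threshold).
#'
#' @seealso [bayesianFdrClassify()], [fixedThresholdClassify()]
#' @export
setClass("DetectionResult",
  representation(
    flags = "ANY",
    f = "ANY",
    thresholdUsed = "numeric",
    rule = "character",
    level = "numeric"
  )
)

setValidity("DetectionResult", function(object) {
  msg <- character()
  if (!object@rule %in% c("fdr", "fixed")) msg <- c(msg, "rule must be 'fdr' or 'fixed'")
  if (!is.logical(object@flags)) msg <- c(msg, "flags must be logical")
  if (object@thresholdUsed < 0 || object@thresholdUsed > 1) {
    msg <- c(msg, "threshold must lie in [0, 1]")
  }
  if (length(object@flags) != length(object@f)) {
    msg <- c(msg, "flags and f must be conformable")
  }
  if (length(msg)) msg else TRUE
})
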