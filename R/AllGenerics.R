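#' @import methods
#' @importFrom stats dnorm dpois quantile rbinom rnorm rpois runif sd var ave
#' @importFrom utils read.csv write.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib baystmix, .registration = TRUE
NULL

#' @importFrom BiocGenerics counts
#' @export
BiocGenerics::counts

#' Number of nodes in a neighbourhood graph
#'
#' @param x a [NeighborGraph-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Edge list of a neighbourhood graph
#'
#' @param x a [NeighborGraph-class] object.
#' @return A two-column integer matrix of unordered node pairs (i < j, 1-based).
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' Per-node neighbour counts
#'
#' @param x a [NeighborGraph-class] object.
#' @return Integer vector of length `nNodes(x)`; entry i is the number of
#'   neighbours of node i (the ICAR conditional precision multiplier).
#' @export
setGeneric("neighborCounts", function(x) standardGeneric("neighborCounts"))

#' Connected-component labels
#'
#' @param x a [NeighborGraph-class] object.
#' @return Integer vector of component ids (1, 2, ...); isolated nodes form
#'   singleton components.
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' Adjacency list
#'
#' @param x a [NeighborGraph-class] object.
#' @return List of integer vectors; element i holds the neighbours of node i.
#' @export
setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))

#' Expected counts (exposure offset)
#'
#' @param x a [SurveillanceCounts-class] object.
#' @return Numeric area-by-time matrix of strictly positive expected counts.
#' @export
setGeneric("expectedCounts", function(x) standardGeneric("expectedCounts"))

#' Posterior allocation probabilities
#'
#' The posterior mean of the binary allocation field z: per area (baseline
#' model) or per area-time cell (proposed model). Low values indicate unusual
#' behaviour.
#'
#' @param x a [PosteriorSamples-class] object.
#' @return Numeric vector (baseline) or area-by-time matrix (proposed) with
#'   entries in \[0, 1\].
#' @export
setGeneric("allocationProb", function(x) standardGeneric("allocationProb"))

#' Declared-unusual flags
#'
#' @param x a [DetectionResult-class] object.
#' @return Logical vector (per area) or area-by-time matrix (per cell);
#'   `TRUE` marks a unit declared unusual.
#' @export
setGeneric("flags", function(x) standardGeneric("flags"))

#' Ground-truth allocation field of a simulated dataset
#'
#' @param x a [SimulatedCounts-class] object.
#' @return Binary area-by-time matrix; 1 = cell generated by the Common model,
#'   0 = injected unusual cell.
#' @export
setGeneric("trueAllocation", function(x) standardGeneric("trueAllocation"))

#' Indices of the injected unusual areas
#'
#' @param x a [SimulatedCounts-class] object.
#' @return Integer vector of area indices (empty for the no-aberration
#'   scenario).
#' @export
setGeneric("unusualAreas", function(x) standardGeneric("unusualAreas"))
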