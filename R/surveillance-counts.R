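#' Construct a surveillance count dataset
#'
#' @param counts area-by-time matrix of non-negative integer event counts.
#' @param expected area-by-time matrix (or a vector recycled across time) of
#'   strictly positive expected counts / exposures.
#' @param areaIds optional character area identifiers (rownames).
#' @param timeLabels optional character time labels (colnames).
#' @return A [SurveillanceCounts-class] object.
#' @examples
#' sc <- surveillanceCounts(matrix(rpois(6, 10), 2), matrix(10, 2, 3))
#' dim(sc)
#' @export
surveillanceCounts <- function(counts, expected, areaIds = NULL,
                               timeLabels = NULL) {
  counts <- as.matrix(counts)
  if (!is.matrix(expected)) {
    expected <- matrix(expected, nrow(counts), ncol(counts))
  }
  if (!identical(dim(counts), dim(expected))) {
    stop("'counts' and 'expected' must have identical dimensions")
  }
  storage.mode(counts) <- "double"
  if (is.null(areaIds)) {
    areaIds <- rownames(counts)
    if (is.null(areaIds)) areaIds <- paste0("area", seq_len(nrow(counts)))
  }
  if (is.null(timeLabels)) {
    timeLabels <- colnames(counts)
    if (is.null(timeLabels)) timeLabels <- paste0("t", seq_len(ncol(counts)))
  }
  dimnames(counts) <- dimnames(expected) <- list(areaIds, timeLabels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, expected = expected)
  )
  new("SurveillanceCounts", se)
}

#' Observed counts
#'
#' @param object a [SurveillanceCounts-class] object.
#' @param ... unused.
#' @return Numeric area-by-time matrix of observed counts.
#' @export
setMethod("counts", "SurveillanceCounts", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname expectedCounts
#' @export
setMethod("expectedCounts", "SurveillanceCounts", function(x) {
  SummarizedExperiment::assay(x, "expected")
})

setMethod("show", "SurveillanceCounts", function(object) {
  cat(class(object), "with", nrow(object), "areas x", ncol(object),
      "time points\n")
  Y <- counts(object); E <- expectedCounts(object)
  cat("  counts: total", sum(Y), " mean SIR", round(sum(Y) / sum(E), 3), "\n")
  if (is(object, "SimulatedCounts")) {
    cat("  scenario:", object@scenario$id %||% "?",
        " unusual areas:", length(object@unusualAreas), "\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname trueAllocation
#' @export
setMethod("trueAllocation", "SimulatedCounts", function(x) x@zTrue)

#' @rdname unusualAreas
#' @export
setMethod("unusualAreas", "SimulatedCounts", function(x) x@unusualAreas)
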