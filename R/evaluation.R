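#' Cross-tabulate declared versus true unusual units
#'
#' Decision units are whole areas for the baseline model (`unit = "area"`,
#' so TP+FP+TN+FN = N) and area-time cells for the proposed model
#' (`unit = "area_time"`, TP+FP+TN+FN = N*T). For per-area accounting an
#' area is truly unusual when any of its time points was injected.
#'
#' @param detected logical flags: per-area vector or per-cell matrix, or a
#'   [DetectionResult-class] object.
#' @param truth ground truth: a [SimulatedCounts-class] object, or a logical
#'   unusual-indicator (vector or matrix) matching the unit convention.
#' @param unit `"area"` or `"area_time"`.
#' @return Named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(detected, truth, unit = c("area_time", "area")) {
  unit <- match.arg(unit)
  if (is(detected, "DetectionResult")) detected <- flags(detected)
  if (is(truth, "SimulatedCounts")) truth <- trueAllocation(truth) == 0
  truth <- truth > 0
  if (unit == "area" && is.matrix(truth)) truth <- apply(truth, 1L, any)
  if (unit == "area" && is.matrix(detected)) detected <- apply(detected, 1L, any)
  if (length(detected) != length(truth)) {
    stop("'detected' and 'truth' must describe the same decision units")
  }
  detected <- as.logical(detected); truth <- as.logical(truth)
  c(TP = sum(detected & truth), FP = sum(detected & !truth),
    TN = sum(!detected & !truth), FN = sum(!detected & truth))
}

#' Detection performance criteria for one replicate
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, proportion of false
#' positives `FP/(TP+FP)` (set to 0 when nothing is declared unusual,
#' TP+FP = 0) and global error `(FP+FN)/(TP+FP+TN+FN)`.
#'
#' @param counts named vector from [confusionCounts()].
#' @return One-row data.frame with columns `sensitivity`, `specificity`,
#'   `fpProportion`, `globalError`. Sensitivity is `NA` (with a warning)
#'   when no unit is truly unusual.
#' @export
detectionMetrics <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  sens <- if (TP + FN == 0) {
    warning("no truly unusual units: sensitivity is undefined")
    NA_real_
  } else TP / (TP + FN)
  spec <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  fpp <- if (TP + FP == 0) 0 else FP / (TP + FP)
  data.frame(sensitivity = sens, specificity = spec, fpProportion = fpp,
             globalError = (FP + FN) / (TP + FP + TN + FN))
}

#' Summarise performance criteria across simulation replicates
#'
#' Per-metric mean and empirical 2.5/97.5 percentiles of the replicate
#' distribution (type-7 quantiles), the format used to report simulation
#' studies of detection performance.
#'
#' @param reports data.frame with one row per replicate (as returned by
#'   [detectionMetrics()]), or a list of such rows.
#' @return data.frame with one row per metric and columns `metric`, `mean`,
#'   `lower2p5`, `upper97p5`, `nReplicates`.
#' @export
summarizeReplicates <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  if (nrow(reports) < 1L) stop("at least one replicate is required")
  metrics <- names(reports)
  do.call(rbind, lapply(metrics, function(m) {
    x <- reports[[m]]
    data.frame(metric = m, mean = mean(x, na.rm = TRUE),
               lower2p5 = as.numeric(quantile(x, 0.025, na.rm = TRUE)),
               upper97p5 = as.numeric(quantile(x, 0.975, na.rm = TRUE)),
               nReplicates = nrow(reports))
  }))
}

#' Summary for the no-aberration scenario
#'
#' With no injected signal, performance is reported as the proportion of
#' replicates in which at least one aberration was declared, and the mean
#' number of declared aberrations among those replicates (0 when no
#' replicate declares anything).
#'
#' @param results list of [DetectionResult-class] objects (or logical flag
#'   vectors/matrices), one per replicate.
#' @return Named numeric vector `c(proportionWithAny, meanCountAmongPositive)`.
#' @export
noAberrationSummary <- function(results) {
  if (!length(results)) stop("at least one replicate is required")
  nFlag <- vapply(results, function(r) {
    if (is(r, "DetectionResult")) r <- flags(r)
    sum(r)
  }, numeric(1))
  any <- nFlag > 0
  c(proportionWithAny = mean(any),
    meanCountAmongPositive = if (any(any)) mean(nFlag[any]) else 0)
}
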