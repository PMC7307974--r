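#' Bayesian FDR classification of allocation probabilities
#'
#' The detection rule of the baseline model. Sorting the posterior
#' allocation probabilities ascending as `f_(1) <= ... <= f_(n)`, `k` is the
#' largest integer such that the mean of the `k` smallest values is below
#' `alpha`; units with `f <= C = f_(k)` are declared unusual, so the
#' expected false discovery proportion among the declared units is
#' controlled at `alpha`. With `k = 0` (even the smallest `f` is at or above
#' `alpha`) nothing is flagged. The cutoff is applied with `<=` so that
#' exactly `k` discoveries are made when the `f` values are distinct; ties
#' at `C` are all flagged.
#'
#' @param f numeric vector (or matrix) of allocation probabilities in
#'   \[0, 1\].
#' @param alpha FDR level in (0, 1); default 0.05.
#' @return A [DetectionResult-class] with rule `"fdr"`.
#' @examples
#' bayesianFdrClassify(c(0.01, 0.02, 0.10, 0.90), alpha = 0.05)
#' @export
bayesianFdrClassify <- function(f, alpha = 0.05) {
  if (length(f) == 0L) stop("'f' must be non-empty")
  if (any(!is.finite(f))) stop("'f' must be finite")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  fs <- sort(as.numeric(f))
  below <- cumsum(fs) / seq_along(fs) < alpha
  k <- if (any(below)) max(which(below)) else 0L
  C <- if (k > 0L) fs[k] else 0
  fl <- if (k > 0L) f <= C else f < 0   # k = 0: flag nothing
  if (is.matrix(f)) dim(fl) <- dim(f)
  new("DetectionResult", flags = fl, f = f, thresholdUsed = C,
      rule = "fdr", level = alpha)
}

#' Fixed-threshold classification of allocation probabilities
#'
#' The detection rule of the proposed model: an area-time cell is declared
#' unusual when its posterior allocation probability falls below a fixed
#' level (by default the conventional 0.05). No multiplicity adjustment is
#' applied; the hierarchical prior on the allocation field performs the
#' smoothing that keeps false positives low.
#'
#' @param f numeric matrix (or vector) of allocation probabilities.
#' @param level threshold in (0, 1); default 0.05.
#' @return A [DetectionResult-class] with rule `"fixed"`.
#' @export
fixedThresholdClassify <- function(f, level = 0.05) {
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  fl <- f < level
  new("DetectionResult", flags = fl, f = f, thresholdUsed = level,
      rule = "fixed", level = level)
}

#' @rdname flags
#' @export
setMethod("flags", "DetectionResult", function(x) x@flags)

setMethod("show", "DetectionResult", function(object) {
  cat("DetectionResult (rule:", object@rule, "at level", object@level,
      "-> cutoff", signif(object@thresholdUsed, 4), "):",
      sum(object@flags), "of", length(object@flags),
      "units declared unusual\n")
})

#' Tidy table of declared-unusual units
#'
#' @param x a [DetectionResult-class] object.
#' @param row.names,optional,... passed for generic compatibility (unused).
#' @return A data.frame with one row per flagged unit: `area`, `time` (`NA`
#'   for per-area detections), `f`, `rule`, `threshold`.
#' @method as.data.frame DetectionResult
#' @export
as.data.frame.DetectionResult <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  fl <- x@flags
  if (is.matrix(fl)) {
    idx <- which(fl, arr.ind = TRUE)
    out <- data.frame(area = idx[, 1L], time = idx[, 2L],
                      f = x@f[fl], rule = x@rule,
                      threshold = x@thresholdUsed)
  } else {
    idx <- which(fl)
    out <- data.frame(area = idx, time = NA_integer_,
                      f = as.numeric(x@f)[idx], rule = x@rule,
                      threshold = x@thresholdUsed)
  }
  out[order(out$area, out$time), , drop = FALSE]
}

#' Write flagged units to CSV
#'
#' @param x a [DetectionResult-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDetectionsCSV <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
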