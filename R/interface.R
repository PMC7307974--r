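#' Read surveillance counts from a long-format CSV
#'
#' Expects columns `area`, `time`, `count`, `expected`, one row per
#' area-time cell, forming a complete grid. Matrices are ordered by sorted
#' area label then sorted time label.
#'
#' @param path CSV file.
#' @return A [SurveillanceCounts-class] object with area/time labels
#'   preserved as dimnames.
#' @export
readCountsCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "time", "count", "expected")
  if (!all(need %in% names(df))) {
    stop("counts CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$count < 0)) {
    stop("negative counts at row(s): ",
         paste(utils::head(which(df$count < 0)), collapse = ", "))
  }
  if (any(df$expected <= 0)) {
    stop("non-positive expected counts at row(s): ",
         paste(utils::head(which(df$expected <= 0)), collapse = ", "))
  }
  areas <- sort(unique(df$area)); times <- sort(unique(df$time))
  key <- paste(df$area, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated area-time cells at row(s): ",
         paste(utils::head(which(duplicated(key))), collapse = ", "))
  }
  full <- expand.grid(area = areas, time = times, stringsAsFactors = FALSE)
  missing <- !(paste(full$area, full$time, sep = "\r") %in% key)
  if (any(missing)) {
    m <- full[missing, , drop = FALSE][1L, ]
    stop("incomplete grid: missing cell (area=", m$area, ", time=", m$time, ")")
  }
  Y <- matrix(NA_real_, length(areas), length(times),
              dimnames = list(as.character(areas), as.character(times)))
  E <- Y
  ri <- match(df$area, areas); ci <- match(df$time, times)
  Y[cbind(ri, ci)] <- df$count
  E[cbind(ri, ci)] <- df$expected
  surveillanceCounts(Y, E)
}

#' Write surveillance counts to a long-format CSV
#'
#' Inverse of [readCountsCSV()]: one row per area-time cell with columns
#' `area`, `time`, `count`, `expected`.
#'
#' @param x a [SurveillanceCounts-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountsCSV <- function(x, path) {
  Y <- counts(x); E <- expectedCounts(x)
  df <- data.frame(
    area = rep(rownames(Y), times = ncol(Y)),
    time = rep(colnames(Y), each = nrow(Y)),
    count = as.vector(Y), expected = as.vector(E))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth allocation of a simulated dataset to CSV
#'
#' One row per area-time cell with columns `area`, `time`, `unusual`
#' (1 = injected unusual cell).
#'
#' @param x a [SimulatedCounts-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthCSV <- function(x, path) {
  z <- trueAllocation(x)
  df <- data.frame(
    area = rep(rownames(x), times = ncol(z)),
    time = rep(colnames(x), each = nrow(z)),
    unusual = as.vector(1 - z))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Aggregate road-segment traffic volume to district level
#'
#' The exposure offset for road-accident surveillance: each segment's
#' traffic volume is its length times its annual average daily flow (AADF),
#' and the district volume is the sum over the segments lying within it,
#' `TV_D = sum over rs in D of length(rs) * AADF(rs)`.
#'
#' @param segments data.frame with columns `district_id`, `length`
#'   (kilometres, > 0) and `aadf` (vehicles/day, > 0).
#' @return Named numeric vector of district traffic volumes; districts with
#'   no segments are absent.
#' @examples
#' aggregateExposure(data.frame(district_id = "D1",
#'                              length = c(2, 3), aadf = c(100, 50)))
#' @export
aggregateExposure <- function(segments) {
  need <- c("district_id", "length", "aadf")
  if (!is.data.frame(segments) || !all(need %in% names(segments)) ||
      nrow(segments) == 0L) {
    stop("'segments' must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(segments$length <= 0)) stop("segment lengths must be positive")
  if (any(segments$aadf <= 0)) stop("AADF values must be positive")
  tv <- tapply(segments$length * segments$aadf, segments$district_id, sum)
  out <- as.numeric(tv)
  names(out) <- names(tv)
  out
}
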