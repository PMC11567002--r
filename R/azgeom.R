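# Active-zone geometry: convex hull, area, center, and event distance
# statistics.

#' Active-zone geometry from event localizations
#'
#' The functional AZ is the convex hull of all fusion events detected in
#' a bouton; its area is the shoelace area of the hull polygon and the AZ
#' center is the arithmetic mean of all event positions. Fewer than three
#' events, or collinear events, give a degenerate AZ of area zero (the
#' center is still defined).
#'
#' @param positions numeric matrix (nEvents x 2) of positions in nm, or a
#'   data.frame with columns `x_nm`, `y_nm`.
#' @param synapseId identifier stored in the result.
#' @param centerMode `"events"` (default) uses the mean of all event
#'   positions; `"polygon"` uses the centroid of the hull polygon.
#'
#' @return An [AZGeometry-class]; hull vertices are ordered
#'   counter-clockwise.
#' @examples
#' g <- azHull(rbind(c(0, 0), c(100, 0), c(0, 100)))
#' azArea(g)     # 5000 nm^2
#' azCenter(g)
#' @export
azHull <- function(positions, synapseId = "synapse",
                   centerMode = c("events", "polygon")) {
  if (is.data.frame(positions))
    positions <- cbind(positions$x_nm, positions$y_nm)
  stopifnot(is.matrix(positions), ncol(positions) == 2L,
            nrow(positions) >= 1L)
  centerMode <- match.arg(centerMode)
  n <- nrow(positions)
  meanCenter <- colMeans(positions)
  hullIdx <- if (n >= 3L) grDevices::chull(positions) else seq_len(n)
  hull <- positions[hullIdx, , drop = FALSE]
  degenerate <- nrow(hull) < 3L
  area <- 0
  if (!degenerate) {
    # chull returns clockwise order; shoelace with sign fix gives CCW
    x <- hull[, 1]; y <- hull[, 2]
    signedArea <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (signedArea < 0) {
      hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
      signedArea <- -signedArea
    }
    area <- signedArea
    if (area <= 0) degenerate <- TRUE   # collinear input
  }
  center <- meanCenter
  if (centerMode == "polygon" && !degenerate) {
    x <- hull[, 1]; y <- hull[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    center <- c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * area)
  }
  colnames(hull) <- c("x", "y")
  new("AZGeometry", synapseId = as.character(synapseId), hull = hull,
      areaNm2 = area, center = unname(center), degenerate = degenerate,
      nEvents = as.integer(n))
}

# Histogram of distances as fraction-of-total with cumulative column.
.distanceDistribution <- function(d, binWidthNm) {
  breaks <- seq(0, (floor(max(d) / binWidthNm) + 1) * binWidthNm,
                by = binWidthNm)
  counts <- graphics::hist(d, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  df <- data.frame(
    bin_lo_nm = breaks[-length(breaks)],
    bin_hi_nm = breaks[-1],
    n = counts,
    fraction = counts / length(d)
  )
  df$cumulative <- cumsum(df$fraction)
  df
}

#' Distances from events to the AZ center
#'
#' @param positions event positions (matrix or data.frame, nm) the
#'   geometry was computed from.
#' @param geometry the matching [AZGeometry-class].
#' @param binWidthNm histogram bin width in nm (default 10).
#'
#' @return list with `distances` (nm, per event, event order preserved)
#'   and `distribution` (data.frame `bin_lo_nm`, `bin_hi_nm`, `n`,
#'   `fraction`, `cumulative`).
#' @export
distancesToCenter <- function(positions, geometry, binWidthNm = 10) {
  if (is.data.frame(positions))
    positions <- cbind(positions$x_nm, positions$y_nm)
  stopifnot(is.matrix(positions), is(geometry, "AZGeometry"),
            binWidthNm > 0)
  ctr <- azCenter(geometry)
  d <- sqrt((positions[, 1] - ctr[1])^2 + (positions[, 2] - ctr[2])^2)
  list(distances = d, distribution = .distanceDistribution(d, binWidthNm))
}

#' Distances between temporally consecutive events
#'
#' Orders one synapse's events by frame (ties keep detection order, i.e.
#' the input row order) and returns the distance between each event and
#' its predecessor.
#'
#' @param events data.frame with columns `frame`, `x_nm`, `y_nm`
#'   (at least 2 rows).
#' @param binWidthNm histogram bin width in nm (default 10).
#'
#' @return list with `distances` (length `nrow(events) - 1`) and
#'   `distribution` as in [distancesToCenter()].
#' @export
consecutiveEventDistances <- function(events, binWidthNm = 10) {
  stopifnot(is.data.frame(events), nrow(events) >= 2L,
            all(c("frame", "x_nm", "y_nm") %in% names(events)))
  ev <- events[order(events$frame), , drop = FALSE]  # stable: ties keep order
  d <- sqrt(diff(ev$x_nm)^2 + diff(ev$y_nm)^2)
  list(distances = d, distribution = .distanceDistribution(d, binWidthNm))
}

#' Compare two groups of event distance distributions
#'
#' Pools the per-event distances of each group and compares them with a
#' two-sample Kolmogorov-Smirnov test, reporting the differences of means
#' and medians (group B minus group A) as effect summaries.
#'
#' @param groupA,groupB numeric vectors of pooled event distances (nm).
#'
#' @return list with `test` (the `ks.test` result), `meanDiff`,
#'   `medianDiff`, and `n` (the two group sizes).
#' @export
centerShiftSummary <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L)
  kt <- suppressWarnings(stats::ks.test(groupA, groupB))
  list(test = kt,
       meanDiff = mean(groupB) - mean(groupA),
       medianDiff = stats::median(groupB) - stats::median(groupA),
       n = c(nA = length(groupA), nB = length(groupB)))
}
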