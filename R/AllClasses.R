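#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Stimulus protocol
#'
#' Describes an electrical field-stimulation protocol and the acquisition
#' timing of the accompanying movie or trace: the number of action
#' potentials delivered, their frequency, the camera frame interval, and
#' the number of pre-stimulus baseline frames.
#'
#' Typical protocols for hippocampal cultures are single-AP stimulation at
#' 1 Hz for 200 s (release-site mapping), 50 AP at 40 Hz, and 100 AP at
#' 10 Hz (pHluorin train responses, imaged at 2 Hz with 30 baseline
#' frames).
#'
#' @slot nPulses integer, number of action potentials (>= 0).
#' @slot frequencyHz numeric, stimulation frequency in Hz (> 0).
#' @slot frameIntervalS numeric, camera frame interval in seconds (> 0).
#' @slot nBaselineFrames integer, frames recorded before the first pulse.
#' @name StimulusProtocol-class
#' @rdname StimulusProtocol
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(
    nPulses = "integer",
    frequencyHz = "numeric",
    frameIntervalS = "numeric",
    nBaselineFrames = "integer"
  )
)

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (length(object@nPulses) != 1L || is.na(object@nPulses) || object@nPulses < 0L)
    msg <- c(msg, "nPulses must be a single non-negative integer")
  if (length(object@frequencyHz) != 1L || !is.finite(object@frequencyHz) ||
      object@frequencyHz <= 0)
    msg <- c(msg, "frequencyHz must be a single positive number")
  if (length(object@frameIntervalS) != 1L || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (length(object@nBaselineFrames) != 1L || is.na(object@nBaselineFrames) ||
      object@nBaselineFrames < 0L)
    msg <- c(msg, "nBaselineFrames must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a stimulus protocol
#'
#' @param nPulses number of action potentials (>= 0).
#' @param frequencyHz stimulation frequency in Hz.
#' @param frameIntervalS camera frame interval in seconds.
#' @param nBaselineFrames number of pre-stimulus baseline frames
#'   (default 30).
#'
#' @return A [StimulusProtocol-class] object.
#' @examples
#' # 100 AP at 10 Hz imaged at 2 Hz, 30 baseline frames
#' StimulusProtocol(100, 10, 0.5)
#' # single-AP mapping protocol: 1 Hz for 200 s at 50 ms frames
#' StimulusProtocol(200, 1, 0.05)
#' @export
StimulusProtocol <- function(nPulses, frequencyHz, frameIntervalS,
                             nBaselineFrames = 30L) {
  new("StimulusProtocol",
      nPulses = as.integer(nPulses),
      frequencyHz = as.numeric(frequencyHz),
      frameIntervalS = as.numeric(frameIntervalS),
      nBaselineFrames = as.integer(nBaselineFrames))
}

#' Ground-truth active zone
#'
#' The hidden parameters of a simulated active zone (AZ): true release-site
#' positions, per-site release probabilities, the AZ radius, and the
#' localization noise applied to observed event positions. Used by the
#' event-stream generator and by parameter-recovery tests.
#'
#' @slot sitePositions numeric matrix (nSites x 2), site centers in nm
#'   relative to the AZ origin.
#' @slot siteRates numeric, per-site probability of release per stimulus,
#'   each in \[0, 1\].
#' @slot azRadiusNm numeric, AZ disk radius in nm.
#' @slot localizationSigmaNm numeric, isotropic Gaussian SD (nm) added to
#'   true positions to produce observed localizations.
#' @name GroundTruthAZ-class
#' @rdname GroundTruthAZ
#' @exportClass GroundTruthAZ
setClass("GroundTruthAZ",
  representation(
    sitePositions = "matrix",
    siteRates = "numeric",
    azRadiusNm = "numeric",
    localizationSigmaNm = "numeric"
  )
)

setValidity("GroundTruthAZ", function(object) {
  msg <- character()
  p <- object@sitePositions
  if (!is.numeric(p) || ncol(p) != 2L)
    msg <- c(msg, "sitePositions must be a numeric matrix with 2 columns")
  else {
    if (nrow(p) != length(object@siteRates))
      msg <- c(msg, "length(siteRates) must equal nrow(sitePositions)")
    r <- sqrt(rowSums(p^2))
    if (any(r > object@azRadiusNm + 1e-9))
      msg <- c(msg, "all site positions must lie within azRadiusNm of the origin")
  }
  if (any(object@siteRates < 0 | object@siteRates > 1))
    msg <- c(msg, "siteRates must lie in [0, 1]")
  if (object@azRadiusNm <= 0)
    msg <- c(msg, "azRadiusNm must be positive")
  if (object@localizationSigmaNm < 0)
    msg <- c(msg, "localizationSigmaNm must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Ground-truth fluorescence trace parameters
#'
#' Hidden parameters of a simulated vGLUT1-pHluorin train response:
#' baseline fluorescence, the fluorescence increase reached at the end of
#' the stimulus train, the endocytic time constant of the post-stimulus
#' single-exponential decay, and the additive noise level.
#'
#' @slot f0 numeric, baseline fluorescence (a.u., > 0).
#' @slot deltaFMax numeric, fluorescence increase at the end of the
#'   stimulus train (a.u., >= 0).
#' @slot tauEndoS numeric, endocytic time constant in seconds (> 0).
#' @slot noiseSd numeric, SD of additive Gaussian noise (a.u., >= 0).
#' @name GroundTruthTrace-class
#' @rdname GroundTruthTrace
#' @exportClass GroundTruthTrace
setClass("GroundTruthTrace",
  representation(
    f0 = "numeric",
    deltaFMax = "numeric",
    tauEndoS = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("GroundTruthTrace", function(object) {
  msg <- character()
  if (object@f0 <= 0) msg <- c(msg, "f0 must be positive")
  if (object@deltaFMax < 0) msg <- c(msg, "deltaFMax must be non-negative")
  if (object@tauEndoS <= 0) msg <- c(msg, "tauEndoS must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname GroundTruthTrace
#' @param f0,deltaFMax,tauEndoS,noiseSd see slot documentation.
#' @return A [GroundTruthTrace-class] object.
#' @export
GroundTruthTrace <- function(f0, deltaFMax, tauEndoS, noiseSd = 0) {
  new("GroundTruthTrace", f0 = as.numeric(f0), deltaFMax = as.numeric(deltaFMax),
      tauEndoS = as.numeric(tauEndoS), noiseSd = as.numeric(noiseSd))
}

#' Fluorescence movie
#'
#' A time-lapse fluorescence movie on the photon-count scale, with its
#' spatial and temporal calibration. Frames are stored as an array
#' \code{[row, col, frame]}. The coordinate convention used throughout the
#' package places the origin at the center of pixel (1, 1), with
#' x = (col - 1) * pixelSizeNm and y = (row - 1) * pixelSizeNm; all
#' positions are reported in nm.
#'
#' @slot frames numeric array, rows x cols x nFrames, non-negative.
#' @slot pixelSizeNm numeric, pixel size in nm (> 0).
#' @slot frameIntervalS numeric, frame interval in seconds (> 0).
#' @name Movie-class
#' @rdname Movie
#' @exportClass Movie
setClass("Movie",
  representation(
    frames = "array",
    pixelSizeNm = "numeric",
    frameIntervalS = "numeric"
  )
)

setValidity("Movie", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-d array [row, col, frame]")
  if (any(object@frames < 0))
    msg <- c(msg, "pixel values must be non-negative")
  if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be positive")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname Movie
#' @param frames 3-d numeric array \code{[row, col, frame]}.
#' @param pixelSizeNm pixel size in nm.
#' @param frameIntervalS frame interval in seconds.
#' @return A [Movie-class] object.
#' @export
Movie <- function(frames, pixelSizeNm, frameIntervalS) {
  new("Movie", frames = frames, pixelSizeNm = as.numeric(pixelSizeNm),
      frameIntervalS = as.numeric(frameIntervalS))
}

#' Fluorescence trace
#'
#' A per-ROI fluorescence time series with its baseline and stimulus
#' windows (1-based frame ranges, both ends included). The baseline window
#' must precede the stimulus window.
#'
#' @slot values numeric, fluorescence per frame (a.u.).
#' @slot frameIntervalS numeric, frame interval in seconds.
#' @slot baselineWindow integer(2), first and last baseline frame.
#' @slot stimulusWindow integer(2), first and last stimulus frame.
#' @name Trace-class
#' @rdname Trace
#' @exportClass Trace
setClass("Trace",
  representation(
    values = "numeric",
    frameIntervalS = "numeric",
    baselineWindow = "integer",
    stimulusWindow = "integer"
  )
)

setValidity("Trace", function(object) {
  msg <- character()
  n <- length(object@values)
  bw <- object@baselineWindow; sw <- object@stimulusWindow
  if (length(bw) != 2L || length(sw) != 2L)
    msg <- c(msg, "baselineWindow and stimulusWindow must each be integer(2)")
  else {
    if (bw[1] < 1L || bw[2] > n || bw[1] > bw[2])
      msg <- c(msg, "baselineWindow out of trace bounds")
    if (sw[1] < 1L || sw[2] > n || sw[1] > sw[2])
      msg <- c(msg, "stimulusWindow out of trace bounds")
    if (length(bw) == 2L && length(sw) == 2L && bw[2] >= sw[1])
      msg <- c(msg, "baseline window must precede the stimulus window")
  }
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname Trace
#' @param values numeric fluorescence values.
#' @param frameIntervalS frame interval in seconds.
#' @param baselineWindow integer(2) frame range of the pre-stimulus
#'   baseline.
#' @param stimulusWindow integer(2) frame range of the stimulus train.
#' @return A [Trace-class] object.
#' @export
Trace <- function(values, frameIntervalS, baselineWindow, stimulusWindow) {
  new("Trace", values = as.numeric(values),
      frameIntervalS = as.numeric(frameIntervalS),
      baselineWindow = as.integer(baselineWindow),
      stimulusWindow = as.integer(stimulusWindow))
}

#' Release-site partition of a synapse's events
#'
#' The result of clustering one synapse's event localizations into release
#' sites: a partition of the events, per-site centroids (member means) and
#' diameters (maximum intra-cluster pairwise distance), and the clustering
#' diameter used. Every cluster diameter is at most the clustering
#' diameter.
#'
#' @slot synapseId character, synapse identifier.
#' @slot positions numeric matrix (nEvents x 2), event positions in nm.
#' @slot assignment integer, cluster index (1..nSites) per event.
#' @slot centroids numeric matrix (nSites x 2), cluster centroids in nm.
#' @slot diametersNm numeric, per-cluster maximum pairwise distance.
#' @slot clusteringDiameterNm numeric, the diameter parameter.
#' @name ReleaseSiteSet-class
#' @rdname ReleaseSiteSet
#' @exportClass ReleaseSiteSet
setClass("ReleaseSiteSet",
  representation(
    synapseId = "character",
    positions = "matrix",
    assignment = "integer",
    centroids = "matrix",
    diametersNm = "numeric",
    clusteringDiameterNm = "numeric"
  )
)

setValidity("ReleaseSiteSet", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  k <- nrow(object@centroids)
  if (length(object@assignment) != n)
    msg <- c(msg, "assignment length must equal the number of events")
  if (n > 0 && !setequal(unique(object@assignment), seq_len(k)))
    msg <- c(msg, "assignment must use every cluster index exactly")
  if (length(object@diametersNm) != k)
    msg <- c(msg, "diametersNm length must equal the number of clusters")
  if (any(object@diametersNm > object@clusteringDiameterNm + 1e-9))
    msg <- c(msg, "cluster diameters must not exceed clusteringDiameterNm")
  if (length(msg)) msg else TRUE
})

#' Active-zone geometry
#'
#' Per-bouton active-zone geometry derived from event localizations: the
#' convex hull of all events (vertices counter-clockwise), its area, and
#' the AZ center defined as the mean position of all events. AZs with
#' fewer than three events, or with all events collinear, are flagged
#' degenerate and carry area 0.
#'
#' @slot synapseId character, synapse identifier.
#' @slot hull numeric matrix, hull vertices (nm), counter-clockwise.
#' @slot areaNm2 numeric, hull area in nm^2.
#' @slot center numeric(2), mean event position in nm.
#' @slot degenerate logical, TRUE if < 3 events or collinear.
#' @slot nEvents integer, number of events the geometry was computed from.
#' @name AZGeometry-class
#' @rdname AZGeometry
#' @exportClass AZGeometry
setClass("AZGeometry",
  representation(
    synapseId = "character",
    hull = "matrix",
    areaNm2 = "numeric",
    center = "numeric",
    degenerate = "logical",
    nEvents = "integer"
  )
)

setValidity("AZGeometry", function(object) {
  msg <- character()
  if (length(object@center) != 2L) msg <- c(msg, "center must be numeric(2)")
  if (object@areaNm2 < 0) msg <- c(msg, "areaNm2 must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Endocytic decay fit
#'
#' Result of fitting the post-stimulus segment of a normalized pHluorin
#' trace to a single-exponential decay
#' \code{fInf + deltaFMax * exp(-(t - tEnd)/tau)}.
#'
#' @slot tauS numeric, endocytic time constant in seconds.
#' @slot deltaFMax numeric, dF/F0 at the end of stimulation relative to
#'   the fitted plateau.
#' @slot fInf numeric, fitted plateau (dF/F0 units).
#' @slot residualNorm numeric, residual sum of squares of the fit.
#' @slot converged logical, FALSE if the optimizer failed or tau pinned at
#'   a bound.
#' @slot message character, diagnostic message.
#' @name EndoFit-class
#' @rdname EndoFit
#' @exportClass EndoFit
setClass("EndoFit",
  representation(
    tauS = "numeric",
    deltaFMax = "numeric",
    fInf = "numeric",
    residualNorm = "numeric",
    converged = "logical",
    message = "character"
  )
)

#' Region-of-interest set
#'
#' Per-synapse regions of interest as simple polygons in nm, in the same
#' coordinate frame as the event localizations. IDs are unique; polygons
#' must be simple (non-self-intersecting).
#'
#' @slot ids character, unique synapse identifiers.
#' @slot polygons list of numeric matrices (nVertices x 2), vertices in nm.
#' @name RoiSet-class
#' @rdname RoiSet
#' @exportClass RoiSet
setClass("RoiSet",
  representation(
    ids = "character",
    polygons = "list"
  )
)

setValidity("RoiSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ROI ids must be unique")
  if (length(object@ids) != length(object@polygons))
    msg <- c(msg, "ids and polygons must have equal length")
  for (i in seq_along(object@polygons)) {
    p <- object@polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L) {
      msg <- c(msg, sprintf("polygon %d must be a matrix with 2 columns and >= 3 vertices", i))
      next
    }
    if (.polygonSelfIntersects(p))
      msg <- c(msg, sprintf("polygon '%s' is self-intersecting", object@ids[i]))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RoiSet
#' @param ids character vector of unique synapse ids.
#' @param polygons list of (nVertices x 2) matrices, vertices in nm.
#' @return A [RoiSet-class] object.
#' @export
RoiSet <- function(ids, polygons) {
  new("RoiSet", ids = as.character(ids), polygons = polygons)
}

# Segment-intersection check for simple-polygon validation. Shared edges
# meeting at a vertex are allowed; proper crossings between non-adjacent
# edges are not.
.polygonSelfIntersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- cross2(c[1], c[2], d[1], d[2], a[1], a[2])
      d2 <- cross2(c[1], c[2], d[1], d[2], b[1], b[2])
      d3 <- cross2(a[1], a[2], b[1], b[2], c[1], c[2])
      d4 <- cross2(a[1], a[2], b[1], b[2], d[1], d[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}
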