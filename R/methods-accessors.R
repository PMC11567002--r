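# Accessor and show methods.

#' @rdname Movie
setMethod("frames", "Movie", function(x) x@frames)

#' @rdname Movie
setMethod("pixelSize", "Movie", function(x) x@pixelSizeNm)

#' @rdname Movie
setMethod("frameInterval", "Movie", function(x) x@frameIntervalS)

#' @rdname Trace
setMethod("frameInterval", "Trace", function(x) x@frameIntervalS)

#' @rdname Trace
setMethod("traceValues", "Trace", function(x) x@values)

#' @rdname Trace
setMethod("baselineWindow", "Trace", function(x) x@baselineWindow)

#' @rdname Trace
setMethod("stimulusWindow", "Trace", function(x) x@stimulusWindow)

#' @rdname Trace
#' @param ... ignored.
setMethod("length", "Trace", function(x) length(x@values))

#' @rdname GroundTruthAZ
setMethod("sitePositions", "GroundTruthAZ", function(x) x@sitePositions)

#' @rdname GroundTruthAZ
setMethod("siteRates", "GroundTruthAZ", function(x) x@siteRates)

#' @rdname GroundTruthAZ
setMethod("azRadius", "GroundTruthAZ", function(x) x@azRadiusNm)

#' @rdname GroundTruthAZ
setMethod("localizationSigma", "GroundTruthAZ", function(x) x@localizationSigmaNm)

#' @rdname GroundTruthAZ
setMethod("nSites", "GroundTruthAZ", function(x) nrow(x@sitePositions))

#' @rdname ReleaseSiteSet
setMethod("nSites", "ReleaseSiteSet", function(x) nrow(x@centroids))

#' @rdname ReleaseSiteSet
setMethod("siteAssignments", "ReleaseSiteSet", function(x) x@assignment)

#' @rdname ReleaseSiteSet
setMethod("siteCentroids", "ReleaseSiteSet", function(x) x@centroids)

#' @rdname ReleaseSiteSet
setMethod("siteDiameters", "ReleaseSiteSet", function(x) x@diametersNm)

#' @rdname ReleaseSiteSet
setMethod("clusteringDiameter", "ReleaseSiteSet", function(x) x@clusteringDiameterNm)

#' @rdname ReleaseSiteSet
setMethod("synapseId", "ReleaseSiteSet", function(x) x@synapseId)

#' @rdname AZGeometry
setMethod("synapseId", "AZGeometry", function(x) x@synapseId)

#' @rdname AZGeometry
setMethod("hullVertices", "AZGeometry", function(x) x@hull)

#' @rdname AZGeometry
setMethod("azArea", "AZGeometry", function(x) x@areaNm2)

#' @rdname AZGeometry
setMethod("azCenter", "AZGeometry", function(x) x@center)

#' @rdname AZGeometry
setMethod("isDegenerate", "AZGeometry", function(x) x@degenerate)

#' @rdname EndoFit
setMethod("endoTau", "EndoFit", function(x) x@tauS)

#' @rdname EndoFit
setMethod("endoDeltaFMax", "EndoFit", function(x) x@deltaFMax)

#' @rdname EndoFit
setMethod("hasConverged", "EndoFit", function(x) x@converged)

#' @rdname StimulusProtocol
setMethod("nPulses", "StimulusProtocol", function(x) x@nPulses)

#' @rdname StimulusProtocol
setMethod("stimulusFrequency", "StimulusProtocol", function(x) x@frequencyHz)

#' @rdname StimulusProtocol
setMethod("frameInterval", "StimulusProtocol", function(x) x@frameIntervalS)

#' @rdname StimulusProtocol
setMethod("nBaselineFrames", "StimulusProtocol", function(x) x@nBaselineFrames)

#' @rdname RoiSet
setMethod("roiIds", "RoiSet", function(x) x@ids)

#' @rdname RoiSet
setMethod("roiPolygons", "RoiSet", function(x) x@polygons)

#' @rdname RoiSet
setMethod("length", "RoiSet", function(x) length(x@ids))

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %d AP at %g Hz, frame interval %g s, %d baseline frames\n",
              object@nPulses, object@frequencyHz, object@frameIntervalS,
              object@nBaselineFrames))
})

setMethod("show", "GroundTruthAZ", function(object) {
  cat(sprintf("GroundTruthAZ: %d sites in a %g-nm-radius AZ, localization sigma %g nm\n",
              nrow(object@sitePositions), object@azRadiusNm,
              object@localizationSigmaNm))
  cat(sprintf("  per-stimulus release rates: %s\n",
              paste(signif(object@siteRates, 3), collapse = ", ")))
})

setMethod("show", "Movie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Movie: %d frames of %d x %d px, %g nm/px, %g s/frame\n",
              d[3], d[1], d[2], object@pixelSizeNm, object@frameIntervalS))
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d frames at %g s/frame; baseline %d-%d, stimulus %d-%d\n",
              length(object@values), object@frameIntervalS,
              object@baselineWindow[1], object@baselineWindow[2],
              object@stimulusWindow[1], object@stimulusWindow[2]))
})

setMethod("show", "ReleaseSiteSet", function(object) {
  cat(sprintf("ReleaseSiteSet '%s': %d events in %d sites (clustering diameter %g nm)\n",
              object@synapseId, nrow(object@positions), nrow(object@centroids),
              object@clusteringDiameterNm))
})

setMethod("show", "AZGeometry", function(object) {
  cat(sprintf("AZGeometry '%s': %d events, area %.0f nm^2%s, center (%.1f, %.1f) nm\n",
              object@synapseId, object@nEvents, object@areaNm2,
              if (object@degenerate) " [degenerate]" else "",
              object@center[1], object@center[2]))
})

setMethod("show", "EndoFit", function(object) {
  cat(sprintf("EndoFit: tau = %.3g s, deltaFMax = %.3g, fInf = %.3g (%s)\n",
              object@tauS, object@deltaFMax, object@fInf,
              if (object@converged) "converged" else
                paste0("NOT converged: ", object@message)))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d polygons (%s)\n", length(object@ids),
              paste(utils::head(object@ids, 5), collapse = ", ")))
})
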