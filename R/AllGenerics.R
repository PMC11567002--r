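# Accessor generics. Slots are never accessed with @ outside the package.

#' @rdname Movie
#' @param x an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname Movie
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname Movie
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname Trace
#' @param x an object.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname Trace
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))

#' @rdname Trace
#' @export
setGeneric("stimulusWindow", function(x) standardGeneric("stimulusWindow"))

#' @rdname GroundTruthAZ
#' @param x an object.
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname GroundTruthAZ
#' @export
setGeneric("siteRates", function(x) standardGeneric("siteRates"))

#' @rdname GroundTruthAZ
#' @export
setGeneric("azRadius", function(x) standardGeneric("azRadius"))

#' @rdname GroundTruthAZ
#' @export
setGeneric("localizationSigma", function(x) standardGeneric("localizationSigma"))

#' @rdname ReleaseSiteSet
#' @param x an object.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname ReleaseSiteSet
#' @export
setGeneric("siteAssignments", function(x) standardGeneric("siteAssignments"))

#' @rdname ReleaseSiteSet
#' @export
setGeneric("siteCentroids", function(x) standardGeneric("siteCentroids"))

#' @rdname ReleaseSiteSet
#' @export
setGeneric("siteDiameters", function(x) standardGeneric("siteDiameters"))

#' @rdname ReleaseSiteSet
#' @export
setGeneric("clusteringDiameter", function(x) standardGeneric("clusteringDiameter"))

#' @rdname ReleaseSiteSet
#' @export
setGeneric("synapseId", function(x) standardGeneric("synapseId"))

#' @rdname AZGeometry
#' @param x an object.
#' @export
setGeneric("hullVertices", function(x) standardGeneric("hullVertices"))

#' @rdname AZGeometry
#' @export
setGeneric("azArea", function(x) standardGeneric("azArea"))

#' @rdname AZGeometry
#' @export
setGeneric("azCenter", function(x) standardGeneric("azCenter"))

#' @rdname AZGeometry
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname EndoFit
#' @param x an object.
#' @export
setGeneric("endoTau", function(x) standardGeneric("endoTau"))

#' @rdname EndoFit
#' @export
setGeneric("endoDeltaFMax", function(x) standardGeneric("endoDeltaFMax"))

#' @rdname EndoFit
#' @export
setGeneric("hasConverged", function(x) standardGeneric("hasConverged"))

#' @rdname StimulusProtocol
#' @param x an object.
#' @export
setGeneric("nPulses", function(x) standardGeneric("nPulses"))

#' @rdname StimulusProtocol
#' @export
setGeneric("stimulusFrequency", function(x) standardGeneric("stimulusFrequency"))

#' @rdname StimulusProtocol
#' @export
setGeneric("nBaselineFrames", function(x) standardGeneric("nBaselineFrames"))

#' @rdname RoiSet
#' @param x an object.
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname RoiSet
#' @export
setGeneric("roiPolygons", function(x) standardGeneric("roiPolygons"))
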