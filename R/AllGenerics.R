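#' @rdname PointPattern-class
#' @param x object
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointPattern-class
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @rdname PointPattern-class
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname PointPattern-class
#' @export
setGeneric("roi", function(x) standardGeneric("roi"))

#' @rdname RegionOfInterest-class
#' @param x object
#' @export
setGeneric("roiArea", function(x) standardGeneric("roiArea"))

#' @rdname SummaryCurve-class
#' @param x object
#' @export
setGeneric("rGrid", function(x) standardGeneric("rGrid"))

#' @rdname SummaryCurve-class
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' @rdname SummaryCurve-class
#' @export
setGeneric("statisticName", function(x) standardGeneric("statisticName"))

#' @rdname EnvelopeResult-class
#' @param x object
#' @export
setGeneric("rejectionIntervals",
           function(x) standardGeneric("rejectionIntervals"))

#' @rdname TrackSet-class
#' @param x object
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname SpotDetectionResult-class
#' @param x object
#' @export
setGeneric("spotCenters", function(x) standardGeneric("spotCenters"))
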