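#' @import methods
NULL

#' Polygonal region of interest with optional holes
#'
#' A planar observation window in micrometres: the traced cell border as the
#' outer ring, with zero or more holes (typically the nucleus) excluded.
#' Coordinates follow the image convention (origin top-left, y increasing
#' downward).  Points exactly on a ring boundary count as inside the ROI.
#'
#' @slot outer numeric matrix (n x 2) of outer-ring vertices in um, open
#'   (first vertex not repeated at the end).
#' @slot holes list of numeric matrices, one per hole ring.
#'
#' @seealso [RegionOfInterest()], [roiArea()], [roiContains()],
#'   [translationOverlap()], [sampleUniform()]
#' @exportClass RegionOfInterest
setClass("RegionOfInterest",
  representation(outer = "matrix", holes = "list"))

setValidity("RegionOfInterest", function(object) {
  out <- object@outer
  if (!is.numeric(out) || ncol(out) != 2 || nrow(out) < 3)
    return("outer ring must be a numeric matrix with >= 3 vertices")
  if (any(!is.finite(out))) return("outer ring has non-finite vertices")
  if (!.ringSimpleCpp(out)) return("outer ring is self-intersecting")
  if (abs(.ringArea(out)) <= 0) return("outer ring has zero area")
  for (h in object@holes) {
    if (!is.numeric(h) || ncol(h) != 2 || nrow(h) < 3)
      return("each hole must be a numeric matrix with >= 3 vertices")
    if (!.ringSimpleCpp(h)) return("a hole ring is self-intersecting")
    if (!all(.containsCpp(list(out), h[, 1], h[, 2])))
      return("holes must lie inside the outer ring")
  }
  if (length(object@holes) > 1) {
    for (i in seq_along(object@holes)[-1]) for (j in seq_len(i - 1)) {
      hi <- object@holes[[i]]; hj <- object@holes[[j]]
      if (any(.containsCpp(list(hj), hi[, 1], hi[, 2])) ||
          any(.containsCpp(list(hi), hj[, 1], hj[, 2])))
        return("holes must be pairwise disjoint")
    }
  }
  if (polyArea(c(list(out), object@holes)) <= 0)
    return("ROI area must be positive")
  TRUE
})

#' Planar marked point pattern tied to a region of interest
#'
#' Spot centres of one fluorescence channel, in micrometres, observed inside
#' a [RegionOfInterest-class].  Every point must pass [roiContains()].
#'
#' @slot coords numeric matrix (n x 2) of point coordinates in um.
#' @slot channel character scalar mark, e.g. "1" or "2".
#' @slot roi the shared [RegionOfInterest-class].
#'
#' @seealso [pointPattern()], [nnFunction()], [kFunction()],
#'   [pairCorrelation()]
#' @exportClass PointPattern
setClass("PointPattern",
  representation(coords = "matrix", channel = "character",
                 roi = "RegionOfInterest"))

setValidity("PointPattern", function(object) {
  xy <- object@coords
  if (!is.numeric(xy) || ncol(xy) != 2)
    return("coords must be a numeric matrix with 2 columns")
  if (nrow(xy) > 0 && any(!is.finite(xy)))
    return("coords must be finite")
  if (length(object@channel) != 1) return("channel must be a scalar mark")
  if (nrow(xy) > 0 &&
      !all(roiContains(object@roi, xy[, 1], xy[, 2])))
    return("all points must lie inside the ROI")
  TRUE
})

#' Spatial summary function on a distance grid
#'
#' One of the bivariate summary statistics G12 (nearest-neighbour function),
#' K12 (Ripley's cross K) or g12 (pair-correlation function), evaluated on a
#' strictly increasing grid of distances r in um.
#'
#' @slot r numeric vector of distances (um), strictly increasing.
#' @slot values numeric vector of estimates, one per r.
#' @slot statistic character, one of "G12", "K12", "g12".
#' @slot metadata list of estimator settings (edge correction, bandwidth,
#'   n1, n2, ROI area, dropped-pair counter).
#'
#' @exportClass SummaryCurve
setClass("SummaryCurve",
  representation(r = "numeric", values = "numeric", statistic = "character",
                 metadata = "list"))

setValidity("SummaryCurve", function(object) {
  if (length(object@r) != length(object@values))
    return("r and values must have equal length")
  if (length(object@r) && (any(object@r < 0) || any(diff(object@r) <= 0)))
    return("r grid must be non-negative and strictly increasing")
  if (!object@statistic %in% c("G12", "K12", "g12"))
    return("statistic must be one of G12, K12, g12")
  TRUE
})

#' Monte-Carlo reference envelope for a summary function
#'
#' Pointwise envelope from N null-model simulations: at every distance r the
#' floor(alpha * N) simulated values deviating most from the pointwise mean
#' are excluded and the band is the min/max of the rest.  The observed curve
#' is stored alongside together with the maximal r-intervals in which it
#' leaves the band (rejection at level alpha).
#'
#' @slot r distance grid (um).
#' @slot lo,hi,mean envelope border and pointwise simulation mean.
#' @slot data observed summary-function values on the same grid.
#' @slot nsim number of simulations N.
#' @slot alpha significance level.
#' @slot statistic which summary function.
#' @slot retained number of simulated values inside the band at each r.
#' @slot intervals two-column matrix of rejection interval endpoints (um).
#' @slot metadata list (null-model spec, seeds, estimator settings).
#'
#' @seealso [buildEnvelope()], [envelopeTest()], [runSMSS()]
#' @exportClass EnvelopeResult
setClass("EnvelopeResult",
  representation(r = "numeric", lo = "numeric", hi = "numeric",
                 mean = "numeric", data = "numeric", nsim = "integer",
                 alpha = "numeric", statistic = "character",
                 retained = "integer", intervals = "matrix",
                 metadata = "list"))

setValidity("EnvelopeResult", function(object) {
  n <- length(object@r)
  if (any(lengths(list(object@lo, object@hi, object@mean, object@data)) != n))
    return("curve slots must share the r grid length")
  if (any(object@lo > object@hi + 1e-12)) return("lo must be <= hi")
  if (object@alpha < 0 || object@alpha >= 1) return("alpha must be in [0, 1)")
  TRUE
})

#' Calibrated single-channel image
#'
#' A single-channel, single-time-point intensity image with its pixel size
#' in um per pixel.  Stored as a base matrix indexed \code{[row, col]} with
#' row 1 at the top; the centre of pixel \code{[i, j]} maps to
#' \code{x = (j - 0.5) * pixelSize}, \code{y = (i - 0.5) * pixelSize}.
#'
#' @slot data numeric matrix of intensities (finite, >= 0).
#' @slot pixelSize um per pixel (> 0).
#' @slot channel character label.
#'
#' @exportClass CalibratedImage
setClass("CalibratedImage",
  representation(data = "matrix", pixelSize = "numeric",
                 channel = "character"))

setValidity("CalibratedImage", function(object) {
  if (any(!is.finite(object@data)) || any(object@data < 0))
    return("intensities must be finite and >= 0")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  TRUE
})

#' Spot detection result
#'
#' Output of [detectSpots()]: the thresholded mask, labelled regions, and
#' the extracted spot centres as a table in um with per-spot size and mean
#' intensity.
#'
#' @slot mask logical/integer matrix, 1 where a spot was detected.
#' @slot labels integer matrix of region labels (0 = background).
#' @slot centers data.frame with columns x_um, y_um, size_px,
#'   mean_intensity.
#' @slot pixelSize um per pixel.
#' @slot saturated logical flag set when the input looked all-saturated.
#'
#' @exportClass SpotDetectionResult
setClass("SpotDetectionResult",
  representation(mask = "matrix", labels = "matrix", centers = "data.frame",
                 pixelSize = "numeric", saturated = "logical"))

setValidity("SpotDetectionResult", function(object) {
  nlab <- length(setdiff(unique(as.integer(object@labels)), 0L))
  if (nrow(object@centers) != nlab)
    return("number of centers must equal number of labelled regions")
  TRUE
})

#' A set of single-particle trajectories
#'
#' Linked trajectories in long format with the uniform frame interval.
#' Gaps (skipped frames from gap closing) are recorded implicitly as missing
#' frames; positions are never interpolated.
#'
#' @slot tracks data.frame with columns track_id, frame, t_s, x_um, y_um,
#'   ordered by track then frame.
#' @slot dt frame interval in seconds.
#'
#' @seealso [linkFrames()], [filterTrajectories()], [trajectoryFeatures()]
#' @exportClass TrackSet
setClass("TrackSet",
  representation(tracks = "data.frame", dt = "numeric"))

setValidity("TrackSet", function(object) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(object@tracks)))
    return(paste("tracks must have columns", paste(need, collapse = ", ")))
  if (length(object@dt) != 1 || object@dt <= 0)
    return("dt must be a positive scalar")
  bad <- vapply(split(object@tracks$frame, object@tracks$track_id),
                function(f) any(diff(f) <= 0), logical(1))
  if (any(bad)) return("frames must be strictly increasing within tracks")
  TRUE
})
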