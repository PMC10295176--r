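# Bivariate spatial summary functions: nearest-neighbour function G12,
# Ripley's cross K-function K12 with translation edge correction, and the
# pair-correlation function g12.

.sameROI <- function(p1, p2) {
  isTRUE(all.equal(p1@roi@outer, p2@roi@outer)) &&
    isTRUE(all.equal(p1@roi@holes, p2@roi@holes))
}

.checkPair <- function(p1, p2) {
  if (npoints(p1) < 1 || npoints(p2) < 1)
    stop("empty point pattern: both patterns need at least one point")
  if (!.sameROI(p1, p2))
    stop("point patterns must share one ROI")
}

.shortExtent <- function(roi) {
  out <- roi@outer
  min(diff(range(out[, 1])), diff(range(out[, 2])))
}

#' Default distance grid for summary functions
#'
#' 512 distances up to one quarter of the shorter ROI extent; starting at 0
#' (G12/K12) or at `from` (g12, which excludes r = 0).
#'
#' @param roi a [RegionOfInterest-class]
#' @param n grid length
#' @param from first grid value
#' @return numeric vector
#' @export
defaultRGrid <- function(roi, n = 512, from = 0) {
  rmax <- .shortExtent(roi) / 4
  seq(from, rmax, length.out = n)
}

#' Bivariate nearest-neighbour function G12
#'
#' Empirical distribution function of the distances from each type-1 point
#' to its nearest type-2 point:
#' G12(r) = (1/n1) sum_i I(d_i <= r).  G12(r) = 0.8 reads as: 80 percent of
#' type-1 points have their nearest type-2 neighbour within r.  No edge
#' correction is applied by default (a reduced-sample border correction is
#' available via `correction = "border"`).
#'
#' @param p1,p2 [PointPattern-class]s sharing one ROI
#' @param r distance grid in um (default [defaultRGrid()])
#' @param correction "none" (default) or "border" (drop type-1 points closer
#'   than r to the ROI bounding box edge).
#' @return a [SummaryCurve-class] with statistic "G12"
#' @examples
#' sq <- RegionOfInterest(cbind(c(0, 20, 20, 0), c(0, 0, 20, 20)))
#' p1 <- pointPattern(c(0, 10), c(0, 0), roi = sq, channel = "1")
#' p2 <- pointPattern(1, 0, roi = sq, channel = "2")
#' curveValues(nnFunction(p1, p2, r = c(0.5, 2, 10)))  # 0, 0.5, 1
#' @export
nnFunction <- function(p1, p2, r = NULL, correction = c("none", "border")) {
  .checkPair(p1, p2)
  correction <- match.arg(correction)
  if (is.null(r)) r <- defaultRGrid(p1@roi)
  d <- .crossNNDistCpp(p1@coords[, 1], p1@coords[, 2],
                       p2@coords[, 1], p2@coords[, 2])
  if (correction == "none") {
    vals <- vapply(r, function(ri) mean(d <= ri), numeric(1))
  } else {
    out <- p1@roi@outer
    bdist <- pmin(p1@coords[, 1] - min(out[, 1]),
                  max(out[, 1]) - p1@coords[, 1],
                  p1@coords[, 2] - min(out[, 2]),
                  max(out[, 2]) - p1@coords[, 2])
    vals <- vapply(r, function(ri) {
      keep <- bdist >= ri
      if (!any(keep)) return(NA_real_)
      mean(d[keep] <= ri)
    }, numeric(1))
  }
  new("SummaryCurve", r = as.numeric(r), values = vals, statistic = "G12",
      metadata = list(correction = correction, n1 = npoints(p1),
                      n2 = npoints(p2), area = roiArea(p1)))
}

# cross-pair distances/weights within rmax, with translation weights
.pairTable <- function(p1, p2, rmax, correction) {
  roi <- p1@roi
  res <- .crossPairsCpp(p1@coords[, 1], p1@coords[, 2],
                        p2@coords[, 1], p2@coords[, 2],
                        rmax, .roiRings(roi), roiArea(roi),
                        correction == "translation",
                        if (is.null(.rectDims(roi))) NULL else .rectDims(roi))
  if (res$dropped > 0)
    warning(sprintf("%d pair(s) dropped: zero translation overlap",
                    res$dropped))
  res
}

#' Bivariate K-function K12 with translation edge correction
#'
#' K12(r) = |Omega| / (n1 n2) * sum_ij b_ij I(||x_i - x_j|| <= r) over
#' cross pairs, with b_ij = |Omega| / |Omega intersect (Omega + (x_j -
#' x_i))| under the translation correction and b_ij = 1 otherwise.  Under
#' independence of the two channels (CSR) K12(r) = pi r^2.
#'
#' @inheritParams nnFunction
#' @param correction "translation" (default) or "none"
#' @return a [SummaryCurve-class] with statistic "K12"
#' @examples
#' sq <- RegionOfInterest(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' p1 <- pointPattern(2, 2, roi = sq, channel = "1")
#' p2 <- pointPattern(2, 4, roi = sq, channel = "2")
#' curveValues(kFunction(p1, p2, r = 3))  # 125
#' @export
kFunction <- function(p1, p2, r = NULL,
                      correction = c("translation", "none")) {
  .checkPair(p1, p2)
  correction <- match.arg(correction)
  if (is.null(r)) r <- defaultRGrid(p1@roi)
  pt <- .pairTable(p1, p2, max(r), correction)
  o <- order(pt$d)
  d <- pt$d[o]; w <- pt$w[o]
  if (length(d) == 0) {
    vals <- numeric(length(r))
  } else {
    cw <- cumsum(w)
    idx <- findInterval(r, d)
    vals <- c(0, cw)[idx + 1L]
  }
  scale <- roiArea(p1) / (npoints(p1) * npoints(p2))
  new("SummaryCurve", r = as.numeric(r), values = as.numeric(vals) * scale,
      statistic = "K12",
      metadata = list(correction = correction, n1 = npoints(p1),
                      n2 = npoints(p2), area = roiArea(p1),
                      dropped = pt$dropped))
}

#' Bivariate pair-correlation function g12
#'
#' Kernel estimate of the derivative form of K12:
#' g12(r) = |Omega| / (2 pi r n1 n2) * sum_ij b_ij kappa_h(r - d_ij) with
#' the Epanechnikov kernel kappa_h.  g12 = 1 under independence (CSR);
#' values above 1 indicate cross-channel attraction at that distance.
#' r = 0 must be excluded from the grid.
#'
#' @inheritParams kFunction
#' @param bandwidth kernel bandwidth h in um; default is Stoyan's rule
#'   h = 0.15 / sqrt(n2 / |Omega|).
#' @return a [SummaryCurve-class] with statistic "g12"
#' @export
pairCorrelation <- function(p1, p2, r = NULL, bandwidth = NULL,
                            correction = c("translation", "none")) {
  .checkPair(p1, p2)
  correction <- match.arg(correction)
  if (is.null(bandwidth))
    bandwidth <- 0.15 / sqrt(npoints(p2) / roiArea(p2))
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(r)) r <- defaultRGrid(p1@roi, from = bandwidth)
  if (any(r <= 0)) stop("g12 grid must exclude r = 0")
  pt <- .pairTable(p1, p2, max(r) + bandwidth, correction)
  o <- order(pt$d)
  d <- pt$d[o]; w <- pt$w[o]
  h <- bandwidth
  vals <- vapply(r, function(ri) {
    lo <- findInterval(ri - h, d) + 1L
    hi <- findInterval(ri + h, d)
    if (hi < lo) return(0)
    u <- (ri - d[lo:hi]) / h
    sum(w[lo:hi] * 0.75 * (1 - u^2)) / h
  }, numeric(1))
  scale <- roiArea(p1) / (2 * pi * r * npoints(p1) * npoints(p2))
  new("SummaryCurve", r = as.numeric(r), values = vals * scale,
      statistic = "g12",
      metadata = list(correction = correction, bandwidth = bandwidth,
                      n1 = npoints(p1), n2 = npoints(p2),
                      area = roiArea(p1), dropped = pt$dropped))
}

#' @rdname SummaryCurve-class
#' @export
setMethod("rGrid", "SummaryCurve", function(x) x@r)

#' @rdname SummaryCurve-class
#' @export
setMethod("curveValues", "SummaryCurve", function(x) x@values)

#' @rdname SummaryCurve-class
#' @export
setMethod("statisticName", "SummaryCurve", function(x) x@statistic)

setMethod("show", "SummaryCurve", function(object) {
  cat(sprintf("SummaryCurve %s: %d r values in [%.3g, %.3g] um\n",
              object@statistic, length(object@r),
              if (length(object@r)) min(object@r) else NA,
              if (length(object@r)) max(object@r) else NA))
})

#' Convert a summary curve to a data.frame
#'
#' @param x a [SummaryCurve-class]
#' @param ... unused
#' @return data.frame with columns r and value
#' @export
setMethod("as.data.frame", "SummaryCurve", function(x, ...) {
  data.frame(r = x@r, value = x@values)
})
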