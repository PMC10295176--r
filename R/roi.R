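# ROI geometry: polygon membership, area, translation overlap, uniform
# sampling.  Exact polygon arithmetic is done in C++ (src/geometry.cpp).

.asRing <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 2) stop("a ring must have two coordinate columns")
  # drop a closing vertex if the ring was supplied closed
  n <- nrow(m)
  if (n > 3 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

.ringArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  0.5 * sum(x * ys - xs * y)
}

.roiRings <- function(roi) c(list(roi@outer), roi@holes)

polyArea <- function(rings) .polyAreaCpp(rings)

# c(W, H) when the ROI is an axis-aligned rectangle without holes, else NULL
.rectDims <- function(roi) {
  if (length(roi@holes) > 0) return(NULL)
  v <- roi@outer
  if (nrow(v) != 4) return(NULL)
  xs <- sort(unique(v[, 1])); ys <- sort(unique(v[, 2]))
  if (length(xs) != 2 || length(ys) != 2) return(NULL)
  ok <- all(v[, 1] %in% xs) && all(v[, 2] %in% ys)
  if (!ok) return(NULL)
  c(diff(xs), diff(ys))
}

#' Construct a region of interest
#'
#' @param outer outer-ring vertices: an (n x 2) matrix or data.frame of x, y
#'   in um.  The ring may be given open or closed; it is stored open.
#' @param holes list of hole rings (same format), e.g. the nucleus.
#' @return a validated [RegionOfInterest-class]
#' @examples
#' sq <- RegionOfInterest(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' roiArea(sq)
#' @export
RegionOfInterest <- function(outer, holes = list()) {
  new("RegionOfInterest", outer = .asRing(outer),
      holes = lapply(holes, .asRing))
}

#' Construct a point pattern inside an ROI
#'
#' @param x numeric vector of x coordinates (um), or an (n x 2) matrix.
#' @param y numeric vector of y coordinates; ignored when x is a matrix.
#' @param roi the [RegionOfInterest-class] the points live in.
#' @param channel mark for the pattern, e.g. "1" or "2".
#' @return a validated [PointPattern-class]
#' @export
pointPattern <- function(x, y = NULL, roi, channel = "1") {
  xy <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (length(xy) == 0) xy <- matrix(numeric(0), 0, 2)
  storage.mode(xy) <- "double"
  dimnames(xy) <- NULL
  new("PointPattern", coords = xy, channel = as.character(channel), roi = roi)
}

#' @rdname RegionOfInterest-class
#' @aliases roiArea,RegionOfInterest-method
#' @export
setMethod("roiArea", "RegionOfInterest",
          function(x) polyArea(.roiRings(x)))

#' @rdname PointPattern-class
#' @export
setMethod("roiArea", "PointPattern", function(x) roiArea(x@roi))

#' @rdname PointPattern-class
#' @export
setMethod("coords", "PointPattern", function(x) x@coords)

#' @rdname PointPattern-class
#' @export
setMethod("npoints", "PointPattern", function(x) nrow(x@coords))

#' @rdname PointPattern-class
#' @export
setMethod("channelLabel", "PointPattern", function(x) x@channel)

#' @rdname PointPattern-class
#' @export
setMethod("roi", "PointPattern", function(x) x@roi)

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf(
    "RegionOfInterest: %d outer vertices, %d hole(s), area %.4g um^2\n",
    nrow(object@outer), length(object@holes), roiArea(object)))
})

setMethod("show", "PointPattern", function(object) {
  cat(sprintf("PointPattern: %d points, channel %s, ROI area %.4g um^2\n",
              npoints(object), object@channel, roiArea(object)))
})

#' Point-in-ROI membership
#'
#' Tests whether points lie inside the ROI (inside the outer ring and not
#' strictly inside any hole).  Points exactly on a ring boundary count as
#' inside.
#'
#' @param roi a [RegionOfInterest-class]
#' @param x,y point coordinates (um); x may be an (n x 2) matrix.
#' @return logical vector
#' @export
roiContains <- function(roi, x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  .containsCpp(.roiRings(roi), as.numeric(x), as.numeric(y))
}

#' Area of overlap between an ROI and its translate
#'
#' Computes |Omega intersect (Omega + v)|, the quantity behind the
#' translation edge-correction weight b_ij = |Omega| / |Omega intersect
#' (Omega + v)| of the bivariate K-function.  Exact polygon clipping; a
#' closed-form fast path is used for axis-aligned rectangles.
#'
#' @param roi a [RegionOfInterest-class]
#' @param v displacement vector c(dx, dy) in um, or an (n x 2) matrix of
#'   displacements.
#' @return numeric vector of overlap areas (um^2)
#' @examples
#' sq <- RegionOfInterest(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' translationOverlap(sq, c(0.5, 0))  # 0.5
#' @export
translationOverlap <- function(roi, v) {
  v <- if (is.matrix(v)) v else matrix(v, ncol = 2)
  wh <- .rectDims(roi)
  if (!is.null(wh)) {
    return(pmax(0, wh[1] - abs(v[, 1])) * pmax(0, wh[2] - abs(v[, 2])))
  }
  .translationOverlapCpp(.roiRings(roi), v[, 1], v[, 2])
}

#' Sample points uniformly inside an ROI
#'
#' Rejection sampling from the bounding box.  Reproducible for a fixed seed;
#' when `seed` is NULL the current RNG state is used (so callers may manage
#' seeding themselves).
#'
#' @param roi a [RegionOfInterest-class]
#' @param n number of points
#' @param seed optional integer seed
#' @param channel mark for the returned pattern
#' @return a [PointPattern-class] with n points
#' @export
sampleUniform <- function(roi, n, seed = NULL, channel = "2") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 0)
  out <- roi@outer
  xr <- range(out[, 1]); yr <- range(out[, 2])
  xs <- numeric(0); ys <- numeric(0)
  need <- n
  while (need > 0) {
    m <- max(64L, ceiling(need * 2.5))
    px <- runif(m, xr[1], xr[2]); py <- runif(m, yr[1], yr[2])
    keep <- roiContains(roi, px, py)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
    need <- n - length(xs)
  }
  pointPattern(xs[seq_len(n)], ys[seq_len(n)], roi = roi, channel = channel)
}
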