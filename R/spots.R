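# Spot detection: undecimated B3-spline a-trous wavelet decomposition,
# per-scale robust thresholding, watershed splitting of touching blobs, and
# intensity-weighted centroid extraction.

#' Construct a calibrated image
#'
#' @param data numeric matrix of intensities, \code{[row, col]}, row 1 at
#'   the top.
#' @param pixelSize um per pixel
#' @param channel channel label
#' @return a [CalibratedImage-class]
#' @export
calibratedImage <- function(data, pixelSize, channel = "1") {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  new("CalibratedImage", data = m, pixelSize = pixelSize,
      channel = as.character(channel))
}

setMethod("show", "CalibratedImage", function(object) {
  cat(sprintf("CalibratedImage: %d x %d px, %.4g um/px, channel %s\n",
              nrow(object@data), ncol(object@data), object@pixelSize,
              object@channel))
})

# whole-sample mirror index (period 2n - 2)
.mirror <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j[j < 0] <- j[j < 0] + p
  j <- ifelse(j >= n, p - j, j)
  as.integer(j + 1L)
}

# separable convolution with the dilated B3 kernel [1,4,6,4,1]/16
.b3smooth <- function(A, d) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * d
  nr <- nrow(A); nc <- ncol(A)
  B <- matrix(0, nr, nc)
  for (k in seq_along(off))
    B <- B + w[k] * A[.mirror(seq_len(nr) + off[k], nr), , drop = FALSE]
  C <- matrix(0, nr, nc)
  for (k in seq_along(off))
    C <- C + w[k] * B[, .mirror(seq_len(nc) + off[k], nc), drop = FALSE]
  C
}

#' A-trous wavelet decomposition
#'
#' Undecimated B3-spline wavelet transform with mirror boundary handling:
#' smoothing kernel [1,4,6,4,1]/16 dilated by 2^(j-1) at scale j, detail
#' planes W_j = A_(j-1) - A_j.  The decomposition is exactly additive:
#' img = A_J + sum_j W_j.
#'
#' @param img a [CalibratedImage-class] or numeric matrix
#' @param nScales number of detail planes J (>= 1)
#' @return list with `planes` (list of J detail matrices) and `residual`
#'   (the smooth plane A_J)
#' @export
atrousDecompose <- function(img, nScales = 3) {
  A <- if (is(img, "CalibratedImage")) img@data else as.matrix(img)
  stopifnot(nScales >= 1)
  support <- 4 * 2^(nScales - 1) + 1
  if (min(dim(A)) < support)
    stop(sprintf("image (%d x %d) smaller than kernel support %d at scale %d",
                 nrow(A), ncol(A), support, nScales))
  planes <- vector("list", nScales)
  for (j in seq_len(nScales)) {
    S <- .b3smooth(A, 2L^(j - 1L))
    planes[[j]] <- A - S
    A <- S
  }
  list(planes = planes, residual = A)
}

#' Detect spots in a calibrated image
#'
#' Wavelet-based spot segmentation: each selected detail plane is hard
#' thresholded at `kSigma` times its robust noise level (MAD/0.6745), the
#' mask is the conjunction of the thresholded planes, components below
#' `minSize` pixels are removed, and (optionally) touching blobs are split
#' by a watershed on the distance transform.  Spot centres are
#' background-subtracted intensity-weighted centroids converted to um.
#'
#' @param img a [CalibratedImage-class]
#' @param scales detail scales used for detection (default 2:3, matched to
#'   spot diameters of roughly 3-10 px)
#' @param kSigma threshold factor (default 3)
#' @param minSize minimum component size in px (default 5)
#' @param split logical; split touching blobs by watershed (default TRUE)
#' @return a [SpotDetectionResult-class]
#' @export
detectSpots <- function(img, scales = 2:3, kSigma = 3, minSize = 5,
                        split = TRUE) {
  stopifnot(is(img, "CalibratedImage"), kSigma > 0, all(scales >= 1))
  A <- img@data
  dec <- atrousDecompose(img, nScales = max(scales))
  mask <- matrix(TRUE, nrow(A), ncol(A))
  for (j in scales) {
    W <- dec$planes[[j]]
    sigma <- mad(W, center = 0)
    mask <- mask & (W > kSigma * sigma)
  }
  saturated <- length(A) > 1 && diff(range(A)) == 0 && max(A) > 0
  if (saturated) warning("image looks saturated (constant intensities)")
  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < minSize)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      mask[lab == 0L] <- FALSE
    }
    if (max(lab) > 0 && split) {
      dm <- EBImage::distmap(ifelse(lab > 0, 1, 0))
      lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    } else {
      lab <- EBImage::bwlabel(ifelse(lab > 0, 1, 0))
    }
  }
  lab <- matrix(as.integer(lab), nrow(A), ncol(A))
  detail <- pmax(A - dec$residual, 0)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  centers <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        size_px = integer(0), mean_intensity = numeric(0))
  if (length(ids)) {
    px <- img@pixelSize
    rows <- row(lab); cols <- col(lab)
    centers <- do.call(rbind, lapply(ids, function(id) {
      sel <- lab == id
      w <- detail[sel]
      if (sum(w) <= 0) w <- rep(1, sum(sel))
      data.frame(
        x_um = (sum(cols[sel] * w) / sum(w) - 0.5) * px,
        y_um = (sum(rows[sel] * w) / sum(w) - 0.5) * px,
        size_px = sum(sel),
        mean_intensity = mean(A[sel]))
    }))
    rownames(centers) <- NULL
  }
  new("SpotDetectionResult", mask = mask, labels = lab, centers = centers,
      pixelSize = img@pixelSize, saturated = saturated)
}

#' @rdname SpotDetectionResult-class
#' @export
setMethod("spotCenters", "SpotDetectionResult", function(x) x@centers)

setMethod("show", "SpotDetectionResult", function(object) {
  cat(sprintf("SpotDetectionResult: %d spot(s)%s\n", nrow(object@centers),
              if (object@saturated) " [saturated]" else ""))
})
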