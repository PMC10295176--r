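# Monte-Carlo reference envelopes under the CSR and transport null models,
# and the pointwise rejection decision.

#' Null-model specification for envelope simulations
#'
#' @slot kind one of "csr", "transport_lognormal", "transport_gaussian".
#' @slot mu,sigma lognormal parameters of the jump length (log scale,
#'   lengths in um); used by "transport_lognormal".
#' @slot stepSigma per-axis Gaussian displacement sd (um); used by
#'   "transport_gaussian".
#' @slot nM target number of simulated type-2 points (count matching);
#'   NA means "match the number of parents".
#'
#' @exportClass NullModelSpec
setClass("NullModelSpec",
  representation(kind = "character", mu = "numeric", sigma = "numeric",
                 stepSigma = "numeric", nM = "numeric"))

setValidity("NullModelSpec", function(object) {
  if (!object@kind %in% c("csr", "transport_lognormal", "transport_gaussian"))
    return("kind must be csr, transport_lognormal or transport_gaussian")
  if (object@kind == "transport_lognormal" && object@sigma <= 0)
    return("lognormal sigma must be > 0")
  if (object@kind == "transport_gaussian" && object@stepSigma <= 0)
    return("stepSigma must be > 0")
  if (!is.na(object@nM) && object@nM < 0) return("nM must be >= 0")
  TRUE
})

#' @rdname NullModelSpec-class
#' @param kind null model kind
#' @param mu,sigma lognormal jump-length parameters (defaults are the
#'   lognormal fitted to lysosomal frame-to-frame jump distances,
#'   mu = -1.87, sigma = 0.94)
#' @param stepSigma per-axis Gaussian displacement sd in um
#' @param nM target simulated count (NA = number of parents)
#' @export
nullModelSpec <- function(kind = c("csr", "transport_lognormal",
                                   "transport_gaussian"),
                          mu = -1.87, sigma = 0.94, stepSigma = 0.2,
                          nM = NA_real_) {
  new("NullModelSpec", kind = match.arg(kind), mu = mu, sigma = sigma,
      stepSigma = stepSigma, nM = as.numeric(nM))
}

#' Simulate one null-model point pattern
#'
#' CSR: `nM` points uniform in the ROI.  Transport: each type-1 point is
#' shifted by a jump vector with lognormal length (or per-axis Gaussian
#' displacement) and uniform direction; a proposal falling outside the ROI
#' is redrawn entirely (new length and angle).  The simulated count is then
#' matched to `nM`: uniform points are appended when nM exceeds the number
#' of parents, or the set is subsampled without replacement when nM is
#' smaller.
#'
#' @param p1 parent [PointPattern-class] (type-1 spots); ignored for CSR
#'   except for its ROI.
#' @param spec a [NullModelSpec-class]
#' @param roi ROI to simulate in (default: the ROI of p1)
#' @param maxRedraw cap on redraws for a single point before an
#'   infeasible-geometry error is raised.
#' @return a [PointPattern-class] of simulated type-2 spots
#' @export
simulateNull <- function(p1, spec, roi = NULL, maxRedraw = 1e5) {
  if (is.null(roi)) roi <- p1@roi
  nM <- spec@nM
  if (spec@kind == "csr") {
    if (is.na(nM)) nM <- npoints(p1)
    return(sampleUniform(roi, nM, channel = "2"))
  }
  n1 <- npoints(p1)
  if (n1 < 1) stop("transport null needs at least one parent point")
  px <- p1@coords[, 1]; py <- p1@coords[, 2]
  x <- rep(NA_real_, n1); y <- rep(NA_real_, n1)
  active <- seq_len(n1)
  iter <- 0L
  while (length(active) > 0) {
    iter <- iter + 1L
    if (iter > maxRedraw)
      stop("infeasible geometry: ROI rejection loop exceeded ", maxRedraw,
           " redraws")
    k <- length(active)
    if (spec@kind == "transport_lognormal") {
      l <- rlnorm(k, spec@mu, spec@sigma)
      th <- runif(k, 0, 2 * pi)
      qx <- px[active] + l * cos(th)
      qy <- py[active] + l * sin(th)
    } else {
      qx <- px[active] + rnorm(k, 0, spec@stepSigma)
      qy <- py[active] + rnorm(k, 0, spec@stepSigma)
    }
    ok <- roiContains(roi, qx, qy)
    x[active[ok]] <- qx[ok]
    y[active[ok]] <- qy[ok]
    active <- active[!ok]
  }
  if (is.na(nM)) nM <- n1
  if (nM > n1) {
    extra <- sampleUniform(roi, nM - n1, channel = "2")
    x <- c(x, extra@coords[, 1]); y <- c(y, extra@coords[, 2])
  } else if (nM < n1) {
    keep <- sample.int(n1, nM)
    x <- x[keep]; y <- y[keep]
  }
  pointPattern(x, y, roi = roi, channel = "2")
}

.computeCurve <- function(statistic, p1, p2, r, bandwidth, correction) {
  switch(statistic,
    G12 = nnFunction(p1, p2, r = r),
    K12 = kFunction(p1, p2, r = r, correction = correction),
    g12 = pairCorrelation(p1, p2, r = r, bandwidth = bandwidth,
                          correction = correction))
}

.rejIntervals <- function(r, outside) {
  if (!any(outside)) return(matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("r_lo", "r_hi"))))
  rl <- rle(outside)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  cbind(r_lo = r[starts[keep]], r_hi = r[ends[keep]])
}

#' Build a pointwise Monte-Carlo envelope
#'
#' At every distance r the floor(alpha * N) simulated values with the
#' largest absolute deviation from the pointwise simulation mean are
#' excluded (ties broken by simulation index); the envelope borders are the
#' minimum and maximum of the retained values.  With N = 100 and
#' alpha = 0.05 the band encloses the 95 least extreme values.  The data
#' curve is not part of the ensemble.
#'
#' @param data observed [SummaryCurve-class]
#' @param sims list of simulated [SummaryCurve-class]s on the same grid
#' @param alpha significance level in [0, 1)
#' @return an [EnvelopeResult-class]
#' @export
buildEnvelope <- function(data, sims, alpha = 0.05) {
  stopifnot(length(sims) >= 2, alpha >= 0, alpha < 1)
  r <- data@r
  for (s in sims)
    if (!isTRUE(all.equal(s@r, r))) stop("mismatched r grids")
  M <- do.call(rbind, lapply(sims, function(s) s@values))
  N <- nrow(M)
  mu <- colMeans(M)
  nExcl <- floor(alpha * N)
  lo <- numeric(length(r)); hi <- numeric(length(r))
  for (j in seq_along(r)) {
    dev <- abs(M[, j] - mu[j])
    # largest deviation first; ties broken by smaller simulation index
    ord <- order(-dev, seq_len(N))
    keep <- if (nExcl > 0) ord[-seq_len(nExcl)] else ord
    lo[j] <- min(M[keep, j]); hi[j] <- max(M[keep, j])
  }
  outside <- data@values < lo | data@values > hi
  new("EnvelopeResult", r = r, lo = lo, hi = hi, mean = mu,
      data = data@values, nsim = as.integer(N), alpha = alpha,
      statistic = data@statistic,
      retained = rep(as.integer(N - nExcl), length(r)),
      intervals = .rejIntervals(r, outside),
      metadata = list(data_metadata = data@metadata))
}

#' Rejection decision from an envelope
#'
#' Returns the maximal r-intervals in which the observed summary function
#' lies outside the envelope, each carrying the verdict "reject at level
#' alpha"; an empty set of intervals means the null model cannot be
#' rejected.
#'
#' @param env an [EnvelopeResult-class]
#' @return list with elements `intervals` (two-column matrix of r ranges),
#'   `reject` (logical) and `verdict` (character)
#' @export
envelopeTest <- function(env) {
  iv <- env@intervals
  reject <- nrow(iv) > 0
  list(intervals = iv, reject = reject,
       verdict = if (reject)
         sprintf("reject at level %g inside %d interval(s)",
                 env@alpha, nrow(iv))
       else "cannot reject")
}

#' @rdname EnvelopeResult-class
#' @export
setMethod("rejectionIntervals", "EnvelopeResult", function(x) x@intervals)

setMethod("show", "EnvelopeResult", function(object) {
  cat(sprintf(
    "EnvelopeResult %s: N = %d, alpha = %g, %d rejection interval(s)\n",
    object@statistic, object@nsim, object@alpha, nrow(object@intervals)))
})

#' @rdname EnvelopeResult-class
#' @param x an EnvelopeResult
#' @param ... unused
#' @export
setMethod("as.data.frame", "EnvelopeResult", function(x, ...) {
  data.frame(r = x@r, lo = x@lo, mean = x@mean, hi = x@hi, data = x@data)
})

#' Run the full envelope analysis for one statistic and null model
#'
#' Computes the observed summary function, simulates `nsim` null point
#' patterns (per-simulation seeds derived from the master seed by a counter
#' scheme), computes their summary functions with identical estimator
#' settings, and assembles the envelope with its rejection intervals.
#' Fully reproducible for a fixed seed.
#'
#' @param p1,p2 observed [PointPattern-class]s (type 1 and type 2)
#' @param statistic "G12", "g12" or "K12"
#' @param spec a [NullModelSpec-class]; its `nM` defaults to the observed
#'   type-2 count
#' @param nsim number of simulations N (default 100)
#' @param alpha significance level (default 0.05)
#' @param seed master integer seed
#' @param r optional distance grid
#' @param bandwidth optional g12 bandwidth (default: Stoyan's rule on p2)
#' @param correction edge correction for K12/g12
#' @return an [EnvelopeResult-class]
#' @export
runSMSS <- function(p1, p2, statistic = c("G12", "g12", "K12"),
                    spec = nullModelSpec("csr"), nsim = 100, alpha = 0.05,
                    seed = 1, r = NULL,
                    bandwidth = NULL, correction = "translation") {
  statistic <- match.arg(statistic)
  if (is.na(spec@nM)) spec@nM <- npoints(p2)
  if (statistic == "g12" && is.null(bandwidth))
    bandwidth <- 0.15 / sqrt(npoints(p2) / roiArea(p2))
  if (is.null(r))
    r <- defaultRGrid(p1@roi,
                      from = if (statistic == "g12") bandwidth else 0)
  dataCurve <- .computeCurve(statistic, p1, p2, r, bandwidth, correction)
  simSeeds <- (as.integer(seed) + seq_len(nsim)) %% .Machine$integer.max
  sims <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    set.seed(simSeeds[i])
    psim <- simulateNull(p1, spec)
    sims[[i]] <- .computeCurve(statistic, p1, psim, r, bandwidth, correction)
  }
  env <- buildEnvelope(dataCurve, sims, alpha = alpha)
  env@metadata <- c(env@metadata,
                    list(null = spec@kind, seed = seed, simSeeds = simSeeds,
                         correction = correction, bandwidth = bandwidth))
  env
}
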