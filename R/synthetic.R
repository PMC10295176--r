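# Seed-deterministic generators for every pipeline stage: paired point
# patterns (independent, transport-displaced, clustered, periodic),
# 2-D trajectories of the four motion archetypes, and spot images.

#' A cell-like default ROI
#'
#' Fixed irregular polygon spanning roughly 40 x 40 um with an off-centre
#' nucleus hole, mimicking a traced cell border with the nucleus excluded.
#'
#' @return a [RegionOfInterest-class]
#' @export
defaultCellROI <- function() {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  rad <- 20 * c(1, 0.85, 0.95, 0.8, 0.9, 1, 0.75, 0.9, 0.95, 0.8, 1, 0.85)
  outer <- cbind(20 + rad * cos(th), 20 + rad * sin(th))
  thh <- seq(0, 2 * pi, length.out = 9)[-9]
  hole <- cbind(16 + 4.5 * cos(thh), 18 + 4 * sin(thh))
  RegionOfInterest(outer, holes = list(hole))
}

#' Generate a paired two-channel point pattern
#'
#' Kinds: `csr_independent` (two independent uniform patterns),
#' `transport_lognormal` / `transport_gaussian` (channel 2 is a displaced
#' copy of channel 1 with lognormal jump length + uniform angle, or
#' per-axis Gaussian displacement, redrawn until inside the ROI),
#' `clustered` (Thomas-type parent-offspring cross pattern) and `periodic`
#' (channel 2 on a jittered square lattice).  Defaults mirror the measured
#' scales: lognormal jumps mu = -1.87, sigma = 0.94 (um).
#'
#' @param kind pattern kind
#' @param roi [RegionOfInterest-class] (default [defaultCellROI()])
#' @param n1 number of channel-1 points (parents)
#' @param n2 number of channel-2 points; for transport kinds the default
#'   (NA) keeps the displaced copy un-matched (n2 = n1)
#' @param mu,sigma lognormal jump-length parameters
#' @param stepSigma per-axis Gaussian displacement sd (um)
#' @param offspring mean number of offspring per parent (clustered)
#' @param scatter offspring scatter sd in um (clustered)
#' @param pitch lattice pitch in um (periodic)
#' @param jitter lattice jitter sd in um (periodic)
#' @param seed integer seed (NULL = use current RNG state)
#' @return list(p1, p2, truth) where truth holds the parent-child map for
#'   transport/clustered kinds
#' @export
genPatternPair <- function(kind = c("csr_independent", "transport_lognormal",
                                    "transport_gaussian", "clustered",
                                    "periodic"),
                           roi = defaultCellROI(), n1 = 300, n2 = NA,
                           mu = -1.87, sigma = 0.94, stepSigma = 0.2,
                           offspring = 5, scatter = 0.3,
                           pitch = 2, jitter = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "csr_independent") {
    p1 <- sampleUniform(roi, n1, channel = "1")
    p2 <- sampleUniform(roi, if (is.na(n2)) n1 else n2, channel = "2")
    return(list(p1 = p1, p2 = p2, truth = NULL))
  }
  if (kind %in% c("transport_lognormal", "transport_gaussian")) {
    p1 <- sampleUniform(roi, n1, channel = "1")
    spec <- nullModelSpec(kind, mu = mu, sigma = sigma,
                          stepSigma = stepSigma, nM = n1)
    p2 <- simulateNull(p1, spec)
    return(list(p1 = p1, p2 = p2,
                truth = list(parent = seq_len(n1), mu = mu, sigma = sigma)))
  }
  if (kind == "clustered") {
    p1 <- sampleUniform(roi, n1, channel = "1")
    kids <- rpois(n1, offspring)
    parent <- rep(seq_len(n1), kids)
    n <- length(parent)
    x <- rep(NA_real_, n); y <- rep(NA_real_, n)
    active <- seq_len(n)
    while (length(active)) {
      qx <- p1@coords[parent[active], 1] + rnorm(length(active), 0, scatter)
      qy <- p1@coords[parent[active], 2] + rnorm(length(active), 0, scatter)
      ok <- roiContains(roi, qx, qy)
      x[active[ok]] <- qx[ok]; y[active[ok]] <- qy[ok]
      active <- active[!ok]
    }
    p2 <- pointPattern(x, y, roi = roi, channel = "2")
    return(list(p1 = p1, p2 = p2, truth = list(parent = parent)))
  }
  # periodic: channel 2 on a jittered square lattice clipped to the ROI
  out <- roi@outer
  gx <- seq(min(out[, 1]), max(out[, 1]), by = pitch)
  gy <- seq(min(out[, 2]), max(out[, 2]), by = pitch)
  lat <- expand.grid(x = gx, y = gy)
  lx <- lat$x + rnorm(nrow(lat), 0, jitter)
  ly <- lat$y + rnorm(nrow(lat), 0, jitter)
  keep <- roiContains(roi, lx, ly)
  p1 <- sampleUniform(roi, n1, channel = "1")
  p2 <- pointPattern(lx[keep], ly[keep], roi = roi, channel = "2")
  list(p1 = p1, p2 = p2, truth = list(pitch = pitch, jitter = jitter))
}

# fractional Gaussian noise by circulant embedding (Davies-Harte); exact
# covariance when the embedding is nonnegative definite (always at desk
# scale for 0 < H < 1)
.fgnSample <- function(n, H, s2 = 1) {
  if (n < 1) return(numeric(0))
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                          abs(k - 1)^(2 * H))
  m <- 1
  while (m < 2 * n) m <- m * 2
  row <- c(g(0:(m / 2)), g((m / 2 - 1):1))
  ev <- Re(fft(row))
  ev[ev < 0] <- 0
  z <- rnorm(m) + 1i * rnorm(m)
  w <- fft(sqrt(ev) * z, inverse = FALSE) / sqrt(m)
  sqrt(s2) * Re(w)[seq_len(n)]
}

#' Generate synthetic 2-D trajectories
#'
#' Kinds: `brownian` (i.i.d. Gaussian increments, per-axis variance
#' 2 D dt), `immobile` (Gaussian localisation jitter around a fixed
#' point), `subdiffusive` (fractional Gaussian increments with Hurst
#' H = alpha0/2, per-axis lag-1 variance 2 D dt^alpha0) and `levy_bimodal`
#' (alternating directed runs at constant speed and diffusive pauses with
#' exponential durations).  Defaults mirror the measurement protocol:
#' dt = 0.827 s, 100 frames.
#'
#' @param kind motion archetype
#' @param nTracks number of trajectories
#' @param nFrames frames per trajectory (default 100)
#' @param dt frame interval in s (default 0.827)
#' @param D diffusion constant um^2/s (brownian/subdiffusive; default the
#'   diffusive-cluster value 0.036)
#' @param alpha0 target anomalous exponent (subdiffusive; default 0.66)
#' @param sigmaLoc localisation jitter sd in um (immobile; default 0.02)
#' @param speed run speed um/s (levy_bimodal; default 1, an active-transport
#'   scale)
#' @param runMean,pauseMean mean run/pause durations in s (levy_bimodal;
#'   defaults emulate short bursts of directed motion between longer
#'   (sub)diffusive intervals)
#' @param pauseD diffusion constant during pauses (levy_bimodal)
#' @param extent side of the square field the starting points are spread
#'   over (um)
#' @param dropout per-detection dropout probability creating gaps
#' @param seed integer seed (NULL = use current RNG state)
#' @return list(detections, truth): a detections data.frame (frame, t_s,
#'   x_um, y_um) and the ground-truth [TrackSet-class]
#' @export
genTrajectories <- function(kind = c("brownian", "immobile", "subdiffusive",
                                     "levy_bimodal"),
                            nTracks = 100, nFrames = 100, dt = 0.827,
                            D = 0.036, alpha0 = 0.66, sigmaLoc = 0.02,
                            speed = 1, runMean = 2, pauseMean = 20,
                            pauseD = 0.005, extent = 40, dropout = 0,
                            seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  oneTrack <- function(id) {
    x0 <- runif(1, 0, extent); y0 <- runif(1, 0, extent)
    if (kind == "brownian") {
      x <- x0 + cumsum(c(0, rnorm(nFrames - 1, 0, sqrt(2 * D * dt))))
      y <- y0 + cumsum(c(0, rnorm(nFrames - 1, 0, sqrt(2 * D * dt))))
    } else if (kind == "immobile") {
      x <- x0 + rnorm(nFrames, 0, sigmaLoc)
      y <- y0 + rnorm(nFrames, 0, sigmaLoc)
    } else if (kind == "subdiffusive") {
      H <- alpha0 / 2
      s2 <- 2 * D * dt^alpha0
      x <- x0 + cumsum(c(0, .fgnSample(nFrames - 1, H, s2)))
      y <- y0 + cumsum(c(0, .fgnSample(nFrames - 1, H, s2)))
    } else {
      x <- numeric(nFrames); y <- numeric(nFrames)
      x[1] <- x0; y[1] <- y0
      running <- runif(1) < 0.5
      left <- rexp(1, 1 / if (running) runMean else pauseMean)
      th <- runif(1, 0, 2 * pi)
      for (f in 2:nFrames) {
        if (left <= 0) {
          running <- !running
          left <- rexp(1, 1 / if (running) runMean else pauseMean)
          th <- runif(1, 0, 2 * pi)
        }
        if (running) {
          x[f] <- x[f - 1] + speed * dt * cos(th)
          y[f] <- y[f - 1] + speed * dt * sin(th)
        } else {
          x[f] <- x[f - 1] + rnorm(1, 0, sqrt(2 * pauseD * dt))
          y[f] <- y[f - 1] + rnorm(1, 0, sqrt(2 * pauseD * dt))
        }
        left <- left - dt
      }
    }
    data.frame(track_id = id, frame = seq_len(nFrames) - 1L,
               t_s = (seq_len(nFrames) - 1) * dt, x_um = x, y_um = y)
  }
  tr <- do.call(rbind, lapply(seq_len(nTracks), oneTrack))
  truth <- new("TrackSet", tracks = tr, dt = dt)
  det <- tr[, c("frame", "t_s", "x_um", "y_um")]
  if (dropout > 0) det <- det[runif(nrow(det)) >= dropout, , drop = FALSE]
  det <- det[order(det$frame), , drop = FALSE]
  rownames(det) <- NULL
  list(detections = det, truth = truth)
}

#' Generate a synthetic spot image
#'
#' Sum of isotropic Gaussian blobs on a constant background with Poisson
#' shot noise.  When `positions` is NULL, `nSpots` positions are drawn
#' uniformly with a minimum pairwise separation.
#'
#' @param nSpots number of spots (ignored when positions given)
#' @param dim image size c(rows, cols) in px
#' @param positions optional (n x 2) matrix of spot centres (x_px, y_px)
#' @param psfSigma PSF sigma in px (default 2)
#' @param amplitude peak amplitude above background (default 50)
#' @param background constant background level (default 10)
#' @param minSep minimum pairwise spot separation in px (default 15)
#' @param margin border kept free of spots in px (default 10)
#' @param pixelSize um per px (default 0.1)
#' @param noise logical; apply Poisson noise (default TRUE)
#' @param seed integer seed (NULL = use current RNG state)
#' @return list(image = [CalibratedImage-class], centers = data.frame with
#'   true centres in px and um)
#' @export
genSpotImage <- function(nSpots = 25, dim = c(128, 128), positions = NULL,
                         psfSigma = 2, amplitude = 50, background = 10,
                         minSep = 15, margin = 10, pixelSize = 0.1,
                         noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  if (is.null(positions)) {
    pos <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pos) < nSpots) {
      tries <- tries + 1
      if (tries > 1e5) stop("cannot place spots with the requested minSep")
      cand <- c(runif(1, margin, nc - margin), runif(1, margin, nr - margin))
      if (nrow(pos) == 0 ||
          min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
            minSep)
        pos <- rbind(pos, cand)
    }
    positions <- pos
  }
  img <- matrix(background, nr, nc)
  cc <- col(img); rr <- row(img)
  for (i in seq_len(nrow(positions))) {
    img <- img + amplitude *
      exp(-(((cc - 0.5) - positions[i, 1])^2 +
            ((rr - 0.5) - positions[i, 2])^2) / (2 * psfSigma^2))
  }
  if (noise) img <- matrix(rpois(length(img), img), nr, nc)
  list(image = calibratedImage(img, pixelSize),
       centers = data.frame(x_px = positions[, 1], y_px = positions[, 2],
                            x_um = positions[, 1] * pixelSize,
                            y_um = positions[, 2] * pixelSize))
}
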