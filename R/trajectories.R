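# Trajectory analytics: frame-to-frame jump distances, lognormal jump fit,
# the 8-feature trajectory descriptor, ensemble MSD and MSD = 4 D t^alpha
# power-law fits, and motion-type assignment.

#' Lognormal fit to jump distances
#'
#' @slot mu log-location (lengths in um)
#' @slot sigma log-scale (>= 0), population MLE
#' @slot nJumps number of jumps used
#' @slot nDropped number of zero jumps dropped before fitting
#' @exportClass JumpDistanceFit
setClass("JumpDistanceFit",
  representation(mu = "numeric", sigma = "numeric", nJumps = "integer",
                 nDropped = "integer"))

setMethod("show", "JumpDistanceFit", function(object) {
  cat(sprintf("JumpDistanceFit: mu = %.4g, sigma = %.4g (n = %d)\n",
              object@mu, object@sigma, object@nJumps))
})

#' Power-law fit to an MSD curve
#'
#' @slot D effective diffusion constant (um^2/s)
#' @slot alpha anomalous exponent
#' @slot r2 coefficient of determination on the log scale
#' @slot n number of trajectories behind the curve
#' @slot se standard errors c(D, alpha) from the linear fit
#' @exportClass MSDFit
setClass("MSDFit",
  representation(D = "numeric", alpha = "numeric", r2 = "numeric",
                 n = "integer", se = "numeric"))

setMethod("show", "MSDFit", function(object) {
  cat(sprintf("MSDFit: D = %.4g um^2/s, alpha = %.4g, R^2 = %.3f (N = %d)\n",
              object@D, object@alpha, object@r2, object@n))
})

.oneTrack <- function(traj) {
  if (is(traj, "TrackSet")) {
    ids <- unique(traj@tracks$track_id)
    if (length(ids) != 1)
      stop("expected a single trajectory; got ", length(ids))
    traj <- traj@tracks
  }
  traj[order(traj$frame), , drop = FALSE]
}

#' Frame-to-frame jump distances
#'
#' Euclidean distances between samples in temporally adjacent frames only;
#' pairs spanning a gap are skipped.  For a [TrackSet-class] the jumps of
#' all trajectories are pooled.
#'
#' @param traj a single-trajectory data.frame (columns frame, x_um, y_um)
#'   or a [TrackSet-class]
#' @return numeric vector of jump lengths (um)
#' @export
jumpDistances <- function(traj) {
  if (is(traj, "TrackSet")) {
    return(unlist(lapply(split(traj@tracks, traj@tracks$track_id),
                         jumpDistances), use.names = FALSE))
  }
  tr <- .oneTrack(traj)
  if (nrow(tr) < 2) return(numeric(0))
  adj <- diff(tr$frame) == 1
  sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[adj]
}

#' Closed-form lognormal MLE for jump distances
#'
#' mu = mean(log l), sigma = population standard deviation of log l
#' (divisor n).  Zero-length jumps are dropped with a warning count.
#'
#' @param jumps numeric vector of jump lengths (um)
#' @return a [JumpDistanceFit-class]
#' @export
fitLognormal <- function(jumps) {
  zero <- jumps <= 0
  nDropped <- sum(zero)
  if (nDropped > 0) {
    warning(sprintf("%d non-positive jump(s) dropped", nDropped))
    jumps <- jumps[!zero]
  }
  if (length(jumps) < 2)
    stop("degenerate jump data: need at least 2 positive jumps")
  lj <- log(jumps)
  mu <- mean(lj)
  sigma <- sqrt(mean((lj - mu)^2))
  new("JumpDistanceFit", mu = mu, sigma = sigma,
      nJumps = length(jumps), nDropped = as.integer(nDropped))
}

# time-averaged MSD at one integer lag; contiguous sample runs only
# (index distance k AND frame distance k means no interior gap)
.sqDispAtLag <- function(tr, k) {
  n <- nrow(tr)
  if (n <= k) return(numeric(0))
  i <- seq_len(n - k)
  ok <- tr$frame[i + k] - tr$frame[i] == k
  ((tr$x_um[i + k] - tr$x_um[i])^2 +
   (tr$y_um[i + k] - tr$y_um[i])^2)[ok]
}

#' Eight-feature trajectory descriptor
#'
#' Mean, standard deviation, skewness and kurtosis (non-excess, normal = 3)
#' of the frame-to-frame jump distances; straightness (net displacement
#' over total path length); corrected sinuosity
#' 2 sqrt(p (1 - c)/(1 + c)) / p with p the mean step and c the mean cosine
#' of the turning angles; average MSD (mean of the time-averaged MSD over
#' lags 1..min(4, n - 1), um^2); and the turn-angle correlation (mean
#' cosine of successive direction changes).
#'
#' @param traj single-trajectory data.frame or single-track
#'   [TrackSet-class]
#' @param dt frame interval in s (kept for interface symmetry; features are
#'   computed per frame)
#' @return named numeric vector of 8 features
#' @export
trajectoryFeatures <- function(traj, dt = 1) {
  tr <- .oneTrack(traj)
  if (nrow(tr) < 4) stop("need at least 4 samples")
  jumps <- jumpDistances(tr)
  if (length(jumps) < 3) stop("need at least 3 frame-to-frame jumps")
  pathLen <- sum(jumps)
  if (pathLen <= 0) stop("zero path length: features undefined")
  m <- mean(jumps)
  v <- mean((jumps - m)^2)
  s <- sqrt(v)
  skew <- if (v > 0) mean((jumps - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((jumps - m)^4) / v^2 else 0
  net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
              (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
  straight <- net / pathLen
  # turning angles between steps in consecutive adjacent-frame pairs
  adj <- which(diff(tr$frame) == 1)
  dx <- diff(tr$x_um); dy <- diff(tr$y_um)
  ang <- atan2(dy[adj], dx[adj])
  consec <- diff(adj) == 1
  turns <- diff(ang)[consec]
  tac <- if (length(turns)) mean(cos(turns)) else NA_real_
  cmean <- tac
  sinu <- if (!is.na(cmean) && cmean > -1)
    2 * sqrt(m * (1 - cmean) / (1 + cmean)) / m else NA_real_
  lags <- seq_len(min(4, nrow(tr) - 1))
  msds <- vapply(lags, function(k) {
    sq <- .sqDispAtLag(tr, k)
    if (length(sq)) mean(sq) else NA_real_
  }, numeric(1))
  avgMSD <- mean(msds, na.rm = TRUE)
  c(jump_mean = m, jump_sd = s, jump_skewness = skew, jump_kurtosis = kurt,
    straightness = straight, sinuosity = sinu, avg_msd = avgMSD,
    turn_angle_corr = tac)
}

#' Feature table for a set of trajectories
#'
#' Applies [trajectoryFeatures()] to every trajectory with at least 4
#' samples, 3 jumps and positive path length; shorter or degenerate
#' trajectories are omitted.
#'
#' @param ts a [TrackSet-class]
#' @return data.frame with track_id and the 8 feature columns
#' @export
featureTable <- function(ts) {
  rows <- lapply(split(ts@tracks, ts@tracks$track_id), function(tr) {
    f <- tryCatch(trajectoryFeatures(tr, ts@dt), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(NULL)
    data.frame(track_id = tr$track_id[1], as.list(f))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Ensemble mean squared displacement
#'
#' For each lag k dt, the average squared displacement pooled over all
#' (trajectory, time-origin) pairs whose sample run does not span a gap.
#'
#' @param ts a [TrackSet-class] (or data.frame of tracks)
#' @param maxLag largest lag in frames
#' @return data.frame with columns lag_s, msd_um2, n_pairs (lags without
#'   any valid pair are dropped with a warning)
#' @export
ensembleMSD <- function(ts, maxLag = 10) {
  tr <- if (is(ts, "TrackSet")) ts@tracks else ts
  dt <- if (is(ts, "TrackSet")) ts@dt else 1
  parts <- split(tr, tr$track_id)
  out <- do.call(rbind, lapply(seq_len(maxLag), function(k) {
    sq <- unlist(lapply(parts, .sqDispAtLag, k = k), use.names = FALSE)
    data.frame(lag_s = k * dt,
               msd_um2 = if (length(sq)) mean(sq) else NA_real_,
               n_pairs = length(sq))
  }))
  if (any(out$n_pairs == 0)) {
    warning("no valid pairs at some lags; curve shortened")
    out <- out[out$n_pairs > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Power-law fit MSD = 4 D t^alpha
#'
#' Least-squares fit of log MSD = log(4 D) + alpha log t.  R^2 and the
#' standard errors are those of the linear fit on the log scale.
#'
#' @param msd data.frame from [ensembleMSD()] (columns lag_s, msd_um2)
#' @param fitLags indices of lags to fit (default
#'   1..min(10, max(3, floor(n/4))))
#' @param n number of trajectories behind the curve (metadata, default NA)
#' @return an [MSDFit-class]
#' @export
fitMSDPowerLaw <- function(msd, fitLags = NULL, n = NA_integer_) {
  if (is.null(fitLags))
    fitLags <- seq_len(min(10, max(3, floor(nrow(msd) / 4))))
  sub <- msd[fitLags, , drop = FALSE]
  if (nrow(sub) < 3) stop("need at least 3 lags in the fit range")
  if (any(!is.finite(sub$msd_um2)) || any(sub$msd_um2 <= 0))
    stop("non-positive MSD value in fit range")
  fit <- lm(log(msd_um2) ~ log(lag_s), data = sub)
  # summary.lm warns on numerically perfect fits (noiseless input is a
  # legitimate use here)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  alpha <- co[2, 1]
  D <- exp(co[1, 1]) / 4
  r2 <- sm$r.squared
  new("MSDFit", D = D, alpha = alpha, r2 = r2, n = as.integer(n),
      se = c(D = D * co[1, 2], alpha = co[2, 2]))
}

#' Motion-type label from the anomalous exponent
#'
#' Boundaries are assigned upward: immobile alpha < 0.3, subdiffusive
#' 0.3 <= alpha < 0.9, diffusive 0.9 <= alpha < 1.3, superdiffusive
#' alpha >= 1.3 (defaults configurable).
#'
#' @param alpha anomalous exponent(s)
#' @param thresholds increasing cut points c(immobile, diffusive_lo,
#'   superdiffusive_lo)
#' @return character vector of labels
#' @export
classifyMotion <- function(alpha, thresholds = c(0.3, 0.9, 1.3)) {
  stopifnot(all(is.finite(alpha)), length(thresholds) == 3,
            !is.unsorted(thresholds))
  as.character(cut(alpha, breaks = c(-Inf, thresholds, Inf), right = FALSE,
                   labels = c("immobile", "subdiffusive", "diffusive",
                              "superdiffusive")))
}
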