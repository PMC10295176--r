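# Shared fixtures and independent brute-force oracles.

unitSquare <- function() {
  RegionOfInterest(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
}

squareROI <- function(w, h = w) {
  RegionOfInterest(cbind(c(0, w, w, 0), c(0, 0, h, h)))
}

squareWithHole <- function() {
  RegionOfInterest(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                   holes = list(cbind(c(0.4, 0.6, 0.6, 0.4),
                                      c(0.4, 0.4, 0.6, 0.6))))
}

# brute-force G12: plain empirical CDF of nearest cross-neighbour distances
bfG12 <- function(xy1, xy2, r) {
  d <- apply(xy1, 1, function(p)
    min(sqrt((xy2[, 1] - p[1])^2 + (xy2[, 2] - p[2])^2)))
  vapply(r, function(ri) mean(d <= ri), numeric(1))
}

# brute-force translation-corrected K12 on a W x H rectangle, using the
# closed-form rectangle overlap written out directly
bfK12rect <- function(xy1, xy2, r, W, H) {
  A <- W * H
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  vals <- numeric(length(r))
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      dx <- xy2[j, 1] - xy1[i, 1]
      dy <- xy2[j, 2] - xy1[i, 2]
      dij <- sqrt(dx^2 + dy^2)
      ov <- max(0, W - abs(dx)) * max(0, H - abs(dy))
      if (ov <= 0) next
      w <- A / ov
      vals <- vals + w * (dij <= r)
    }
  }
  vals * A / (n1 * n2)
}

# dense-grid rasterized overlap estimate (independent of polygon clipping)
rasterOverlap <- function(roi, v, n = 700) {
  out <- roi@outer
  xs <- seq(min(out[, 1]), max(out[, 1]), length.out = n)
  ys <- seq(min(out[, 2]), max(out[, 2]), length.out = n)
  g <- expand.grid(x = xs, y = ys)
  inA <- roiContains(roi, g$x, g$y)
  inB <- roiContains(roi, g$x - v[1], g$y - v[2])
  mean(inA & inB) * diff(range(out[, 1])) * diff(range(out[, 2]))
}

# mean pointwise Jaccard overlap of two envelope bands
envelopeOverlapFraction <- function(e1, e2) {
  num <- pmax(0, pmin(e1@hi, e2@hi) - pmax(e1@lo, e2@lo))
  den <- pmax(e1@hi, e2@hi) - pmin(e1@lo, e2@lo)
  mean(ifelse(den > 0, num / den, 1))
}

makeTrackSet <- function(frames, x, y, dt = 0.827, id = 1L) {
  new("TrackSet",
      tracks = data.frame(track_id = id, frame = frames, t_s = frames * dt,
                          x_um = x, y_um = y),
      dt = dt)
}
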