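# Single-particle tracking: frame-to-frame linking by optimal assignment
# with a non-link alternative, followed by gap closing between track ends
# and starts.  Merging and splitting are disregarded.

.BIG <- 1e12

# augmented assignment between n sources and m targets; linkCost is n x m
# with NA for forbidden pairs; altCost prices the non-link alternative.
# Returns integer vector over sources: target index or NA.
.lapLink <- function(linkCost, altCost) {
  n <- nrow(linkCost); m <- ncol(linkCost)
  if (n == 0) return(integer(0))
  sz <- n + m
  C <- matrix(.BIG, sz, sz)
  tl <- linkCost
  tl[is.na(tl)] <- .BIG
  C[seq_len(n), seq_len(m)] <- tl
  for (i in seq_len(n)) C[i, m + i] <- altCost
  for (j in seq_len(m)) C[n + j, j] <- altCost
  # lower-right block: allow "unused" pairings at zero cost
  C[n + seq_len(m), m + seq_len(n)] <- 0
  asg <- .solveLAPCpp(C)
  out <- rep(NA_integer_, n)
  hit <- asg[seq_len(n)]
  ok <- hit <= m & !is.na(hit)
  ok[ok] <- linkCost[cbind(which(ok), hit[ok])] < .BIG &
    !is.na(linkCost[cbind(which(ok), hit[ok])])
  out[ok] <- hit[ok]
  out
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment minimising total squared displacement among
#' candidate pairs within `maxLink`, with the non-link alternative priced at
#' `maxLink^2` (Hungarian method on the augmented cost matrix).  Track ends
#' are then matched to track starts up to `maxGap` skipped frames later and
#' within `gapDist` by a second assignment (non-link cost `gapDist^2`).
#' Skipped frames are recorded as gaps; positions are never interpolated.
#' Defaults follow the protocol used for lysosome tracking: 1 um linking
#' distance, 2-frame maximum gap, 2 um gap-closing distance.
#'
#' @param dets data.frame of detections with columns frame, t_s, x_um,
#'   y_um (0-based or 1-based frames, uniform interval).
#' @param maxLink frame-to-frame linking distance in um
#' @param maxGap maximum number of skipped frames closed by gap closing
#' @param gapDist gap-closing distance in um
#' @return a [TrackSet-class]
#' @export
linkFrames <- function(dets, maxLink = 1, maxGap = 2, gapDist = 2) {
  stopifnot(maxLink > 0, maxGap >= 0, gapDist > 0,
            all(c("frame", "t_s", "x_um", "y_um") %in% names(dets)))
  dets <- dets[order(dets$frame), , drop = FALSE]
  nd <- nrow(dets)
  if (nd == 0) return(new("TrackSet", tracks = data.frame(
    track_id = integer(0), frame = integer(0), t_s = numeric(0),
    x_um = numeric(0), y_um = numeric(0)), dt = 1))
  uf <- sort(unique(dets$frame))
  ut <- vapply(uf, function(f) dets$t_s[match(f, dets$frame)], numeric(1))
  dt <- if (length(uf) > 1) median(diff(ut) / diff(uf)) else 1
  byFrame <- split(seq_len(nd), dets$frame)
  succ <- rep(NA_integer_, nd)  # detection-level forward link
  for (k in seq_len(length(uf) - 1)) {
    if (uf[k + 1] - uf[k] != 1) next
    src <- byFrame[[as.character(uf[k])]]
    tgt <- byFrame[[as.character(uf[k + 1])]]
    dx <- outer(dets$x_um[src], dets$x_um[tgt], "-")
    dy <- outer(dets$y_um[src], dets$y_um[tgt], "-")
    d2 <- dx^2 + dy^2
    d2[d2 > maxLink^2] <- NA
    link <- .lapLink(matrix(d2, length(src), length(tgt)), maxLink^2)
    succ[src[!is.na(link)]] <- tgt[link[!is.na(link)]]
  }
  # build segments
  isStart <- rep(TRUE, nd)
  isStart[succ[!is.na(succ)]] <- FALSE
  segs <- lapply(which(isStart), function(i) {
    idx <- i
    while (!is.na(succ[idx[length(idx)]])) idx <- c(idx, succ[idx[length(idx)]])
    idx
  })
  # gap closing: segment end -> segment start, 2..maxGap+1 frames later
  if (maxGap > 0 && length(segs) > 1) {
    endIdx <- vapply(segs, function(s) s[length(s)], integer(1))
    startIdx <- vapply(segs, function(s) s[1], integer(1))
    fEnd <- dets$frame[endIdx]; fStart <- dets$frame[startIdx]
    dx <- outer(dets$x_um[endIdx], dets$x_um[startIdx], "-")
    dy <- outer(dets$y_um[endIdx], dets$y_um[startIdx], "-")
    d2 <- dx^2 + dy^2
    gap <- outer(fEnd, fStart, function(a, b) b - a)
    d2[gap < 2 | gap > maxGap + 1 | d2 > gapDist^2] <- NA
    diag(d2) <- NA
    link <- .lapLink(d2, gapDist^2)
    nextSeg <- link  # per segment: index of appended segment
    prevLinked <- rep(FALSE, length(segs))
    prevLinked[link[!is.na(link)]] <- TRUE
    merged <- list()
    for (s in seq_along(segs)) {
      if (prevLinked[s]) next
      chain <- segs[[s]]
      cur <- s
      while (!is.na(nextSeg[cur])) {
        cur <- nextSeg[cur]
        chain <- c(chain, segs[[cur]])
      }
      merged[[length(merged) + 1]] <- chain
    }
    segs <- merged
  }
  tr <- do.call(rbind, lapply(seq_along(segs), function(id) {
    idx <- segs[[id]]
    data.frame(track_id = id, frame = dets$frame[idx], t_s = dets$t_s[idx],
               x_um = dets$x_um[idx], y_um = dets$y_um[idx])
  }))
  rownames(tr) <- NULL
  new("TrackSet", tracks = tr, dt = dt)
}

#' @rdname TrackSet-class
#' @export
setMethod("tracks", "TrackSet", function(x) x@tracks)

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d trajectory(ies), %d samples, dt = %.4g s\n",
              length(unique(object@tracks$track_id)), nrow(object@tracks),
              object@dt))
})

.gapCount <- function(frames) sum(diff(frames) - 1)

#' Filter trajectories by length and gap count
#'
#' Keeps trajectories with at least `minPoints` samples (detections) and at
#' most `maxGaps` gaps; the defaults reproduce the exclusion rule
#' "fewer than ten time points or more than five gaps".
#'
#' @param ts a [TrackSet-class]
#' @param minPoints minimum number of samples (default 10)
#' @param maxGaps maximum number of gaps (default 5)
#' @return a filtered [TrackSet-class] (track order preserved)
#' @export
filterTrajectories <- function(ts, minPoints = 10, maxGaps = 5) {
  tr <- ts@tracks
  keep <- vapply(split(tr$frame, tr$track_id), function(f) {
    length(f) >= minPoints && .gapCount(f) <= maxGaps
  }, logical(1))
  ids <- names(keep)[keep]
  out <- tr[as.character(tr$track_id) %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  new("TrackSet", tracks = out, dt = ts@dt)
}
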