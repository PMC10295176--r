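detFrame <- function(frame, x, y, dt = 1) {
  data.frame(frame = frame, t_s = frame * dt, x_um = x, y_um = y)
}

test_that("a single drifting detection makes one full-length track", {
  d <- detFrame(0:19, 0.1 * (0:19), rep(0, 20))
  ts <- linkFrames(d)
  tr <- tracks(ts)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)
})

test_that("detections farther apart than the linking distance start new
           tracks", {
  d <- detFrame(0:3, c(0, 1.5, 3.0, 4.5), rep(0, 4))
  ts <- linkFrames(d, maxLink = 1)
  expect_equal(length(unique(tracks(ts)$track_id)), 4)
})

test_that("crossing particles get the cost-minimal assignment", {
  # two particles cross on parallel lanes; lane keeping is cost-minimal
  d <- rbind(detFrame(0:4, c(0, 1, 2, 3, 4), rep(0, 5)),
             detFrame(0:4, c(4, 3, 2, 1, 0), rep(0.5, 5)))
  d <- d[order(d$frame), ]
  ts <- linkFrames(d, maxLink = 2)
  tr <- tracks(ts)
  expect_equal(length(unique(tr$track_id)), 2)
  # brute force over the two possible frame-pair assignments at each step
  for (f in 0:3) {
    a <- d[d$frame == f, ]; b <- d[d$frame == f + 1, ]
    costKeep <- (a$x_um[1] - b$x_um[1])^2 + (a$y_um[1] - b$y_um[1])^2 +
      (a$x_um[2] - b$x_um[2])^2 + (a$y_um[2] - b$y_um[2])^2
    costSwap <- (a$x_um[1] - b$x_um[2])^2 + (a$y_um[1] - b$y_um[2])^2 +
      (a$x_um[2] - b$x_um[1])^2 + (a$y_um[2] - b$y_um[1])^2
    expect_lte(costKeep, costSwap)  # the lane-keeping option is optimal
  }
  lane0 <- tr[tr$y_um == 0, ]
  expect_equal(length(unique(lane0$track_id)), 1)
})

test_that("gap closing bridges short detection dropouts within distance", {
  d <- detFrame(c(0, 1, 2, 5, 6, 3, 4), 0, 0)[1:5, ]  # frames 0,1,2,5,6
  ts <- linkFrames(d, maxLink = 1, maxGap = 2, gapDist = 2)
  expect_equal(length(unique(tracks(ts)$track_id)), 1)
  # a 3-frame hole exceeds maxGap = 2
  d2 <- detFrame(c(0, 1, 2, 6, 7), 0, 0)
  ts2 <- linkFrames(d2, maxLink = 1, maxGap = 2, gapDist = 2)
  expect_equal(length(unique(tracks(ts2)$track_id)), 2)
})

test_that("trajectory filters apply the boundary rules exactly", {
  ninePts <- makeTrackSet(0:8, rep(0, 9), rep(0, 9))
  expect_equal(nrow(tracks(filterTrajectories(ninePts))), 0)
  tenPts <- makeTrackSet(0:9, rep(0, 10), rep(0, 10))
  expect_equal(nrow(tracks(filterTrajectories(tenPts))), 10)
  # 12 samples spread so that the track carries 6 gaps -> excluded
  sixGaps <- makeTrackSet(c(0:5, 7, 9, 11, 13, 15, 17), rep(0, 12),
                          rep(0, 12))
  expect_equal(nrow(tracks(filterTrajectories(sixGaps))), 0)
  fiveGaps <- makeTrackSet(c(0:6, 8, 10, 12, 14, 16), rep(0, 12),
                           rep(0, 12))
  expect_equal(nrow(tracks(filterTrajectories(fiveGaps))), 12)
})

test_that("well-separated walkers are recovered exactly and detections are
           never reused", {
  g <- genTrajectories("brownian", nTracks = 15, nFrames = 40, D = 0.004,
                       extent = 300, seed = 19)
  ts <- linkFrames(g$detections)
  tr <- tracks(ts)
  expect_equal(length(unique(tr$track_id)), 15)
  expect_equal(nrow(tr), nrow(g$detections))
  expect_false(any(duplicated(tr[, c("frame", "x_um", "y_um")])))
  # per-frame positions coincide with the ground truth
  truth <- tracks(g$truth)
  key <- function(d) paste(d$frame, round(d$x_um, 9), round(d$y_um, 9))
  expect_setequal(key(tr), key(truth))
  # recovered partition matches the true partition
  expect_equal(length(unique(paste(tr$track_id,
    truth$track_id[match(key(tr), key(truth))]))), 15)
})

test_that("optimal linking never costs more than greedy nearest neighbour", {
  set.seed(91)
  for (rep in 1:5) {
    a <- cbind(runif(6, 0, 5), runif(6, 0, 5))
    b <- a + matrix(rnorm(12, 0, 0.4), 6, 2)
    d <- rbind(detFrame(rep(0, 6), a[, 1], a[, 2]),
               detFrame(rep(1, 6), b[, 1], b[, 2]))
    ts <- linkFrames(d, maxLink = 2)
    tr <- tracks(ts)
    linked <- tr[order(tr$track_id, tr$frame), ]
    cost <- 0
    for (id in unique(linked$track_id)) {
      sub <- linked[linked$track_id == id, ]
      if (nrow(sub) == 2)
        cost <- cost + sum((sub$x_um[2] - sub$x_um[1])^2 +
                           (sub$y_um[2] - sub$y_um[1])^2)
      else cost <- cost + 4  # unlinked detection pays maxLink^2
    }
    # greedy assignment
    avail <- rep(TRUE, 6); gcost <- 0
    for (i in 1:6) {
      dd <- sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)
      dd[!avail] <- Inf
      j <- which.min(dd)
      if (dd[j] <= 2) { gcost <- gcost + dd[j]^2; avail[j] <- FALSE }
      else gcost <- gcost + 4
    }
    gcost <- gcost + 4 * sum(avail) - 4 * sum(avail)  # ends unmatched free
    expect_lte(cost, gcost + 1e-9)
  }
})
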