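test_that("jump distances use temporally adjacent frames only", {
  expect_equal(jumpDistances(data.frame(frame = 1:2, x_um = c(0, 3),
                                        y_um = c(0, 4))), 5)
  j <- jumpDistances(data.frame(frame = c(1, 2, 4), x_um = c(0, 3, 10),
                                y_um = c(0, 4, 10)))
  expect_equal(j, 5)  # the 2 -> 4 pair spans a gap and is skipped
  still <- jumpDistances(data.frame(frame = 1:5, x_um = rep(1, 5),
                                    y_um = rep(2, 5)))
  expect_equal(still, rep(0, 4))
})

test_that("lognormal MLE is closed-form exact and recovers parameters", {
  expect_warning(f0 <- fitLognormal(c(exp(2), exp(2), exp(2), 0)),
                 "dropped")
  expect_equal(f0@mu, 2)
  expect_equal(f0@sigma, 0)
  expect_error(suppressWarnings(fitLognormal(c(0, 0))), "degenerate")
  set.seed(101)
  x <- rlnorm(2e5, -1.87, 0.94)
  f <- fitLognormal(x)
  n <- length(x)
  expect_lt(abs(f@mu - (-1.87)), 3 * 0.94 / sqrt(n))
  expect_lt(abs(f@sigma - 0.94), 3 * 0.94 / sqrt(2 * n))
  # agreement with direct numerical likelihood maximization
  nll <- function(p) -sum(stats::dlnorm(x[1:5000], p[1], p[2], log = TRUE))
  opt <- optim(c(0, 1), nll)
  f5 <- fitLognormal(x[1:5000])
  expect_lt(abs(f5@mu - opt$par[1]), 1e-3)
  expect_lt(abs(f5@sigma - opt$par[2]), 1e-3)
  # KS: the fitted model is consistent with its own sample
  ks <- suppressWarnings(stats::ks.test(x, "plnorm", f@mu, f@sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("features match hand computation on the square path", {
  f <- trajectoryFeatures(data.frame(frame = 1:4, x_um = c(0, 1, 1, 0),
                                     y_um = c(0, 0, 1, 1)))
  expect_equal(unname(f["straightness"]), 1 / 3)
  expect_equal(unname(f["turn_angle_corr"]), 0)
  expect_equal(unname(f["jump_mean"]), 1)
  expect_equal(unname(f["jump_sd"]), 0)
  # avg MSD over lags 1..3: (1 + 2 + 1) / 3
  expect_equal(unname(f["avg_msd"]), 4 / 3)
})

test_that("a straight uniform walk has straightness one and perfect turn
           correlation", {
  f <- trajectoryFeatures(data.frame(frame = 0:9, x_um = 0.3 * (0:9),
                                     y_um = rep(0, 10)))
  expect_equal(unname(f["straightness"]), 1)
  expect_equal(unname(f["turn_angle_corr"]), 1)
  expect_equal(unname(f["jump_sd"]), 0)
})

test_that("Brownian increments have vanishing mean turn-angle correlation", {
  g <- genTrajectories("brownian", nTracks = 300, nFrames = 50, D = 0.05,
                       seed = 71)
  fe <- featureTable(g$truth)
  tac <- fe$turn_angle_corr
  expect_lt(abs(mean(tac)), 3 * sd(tac) / sqrt(length(tac)))
})

test_that("degenerate trajectories raise feature errors", {
  expect_error(trajectoryFeatures(data.frame(frame = 1:3, x_um = 1:3,
                                             y_um = 1:3)), "4 samples")
  expect_error(trajectoryFeatures(data.frame(frame = 1:4, x_um = rep(0, 4),
                                             y_um = rep(0, 4))),
               "zero path length")
})

test_that("ensemble MSD matches closed forms", {
  still <- makeTrackSet(0:9, rep(2, 10), rep(3, 10))
  msd <- ensembleMSD(still, maxLag = 5)
  expect_equal(msd$msd_um2, rep(0, 5))
  v <- 0.2; dt <- 0.827
  ball <- makeTrackSet(0:19, v * dt * (0:19), rep(0, 20), dt = dt)
  msdB <- ensembleMSD(ball, maxLag = 8)
  expect_equal(msdB$msd_um2, (v * msdB$lag_s)^2, tolerance = 1e-12)
  g <- genTrajectories("brownian", nTracks = 1000, nFrames = 40, D = 0.05,
                       dt = 0.827, seed = 81)
  msdG <- ensembleMSD(g$truth, maxLag = 10)
  expect_lt(max(abs(msdG$msd_um2 / (4 * 0.05 * msdG$lag_s) - 1)), 0.03)
})

test_that("single-trajectory ensemble MSD equals the time-averaged MSD", {
  g <- genTrajectories("brownian", nTracks = 1, nFrames = 30, D = 0.02,
                       seed = 9)
  tr <- tracks(g$truth)
  msd <- ensembleMSD(g$truth, maxLag = 5)
  for (k in 1:5) {
    n <- nrow(tr)
    i <- seq_len(n - k)
    ta <- mean((tr$x_um[i + k] - tr$x_um[i])^2 +
               (tr$y_um[i + k] - tr$y_um[i])^2)
    expect_equal(msd$msd_um2[k], ta)
  }
})

test_that("power-law fits are exact on noiseless curves and
           scale-equivariant", {
  t <- 0.827 * (1:10)
  exact <- data.frame(lag_s = t, msd_um2 = 4 * 0.05 * t)
  f <- fitMSDPowerLaw(exact, fitLags = 1:10)
  expect_equal(f@D, 0.05, tolerance = 1e-12)
  expect_equal(f@alpha, 1, tolerance = 1e-12)
  expect_equal(f@r2, 1)
  ball <- data.frame(lag_s = t, msd_um2 = (0.2 * t)^2)
  fb <- fitMSDPowerLaw(ball, fitLags = 1:10)
  expect_equal(fb@alpha, 2, tolerance = 1e-12)
  expect_equal(fb@D, 0.01, tolerance = 1e-12)
  # coordinate scaling by c multiplies D by c^2, alpha unchanged
  scaled <- data.frame(lag_s = t, msd_um2 = 9 * exact$msd_um2)
  fs <- fitMSDPowerLaw(scaled, fitLags = 1:10)
  expect_equal(fs@D, 9 * f@D, tolerance = 1e-10)
  expect_equal(fs@alpha, f@alpha, tolerance = 1e-10)
  expect_error(fitMSDPowerLaw(data.frame(lag_s = t[1:3],
                                         msd_um2 = c(1, 0, 2))),
               "non-positive")
})

test_that("subdiffusive generation recovers the target exponent", {
  for (a0 in c(0.5, 0.7)) {
    g <- genTrajectories("subdiffusive", nTracks = 500, nFrames = 100,
                         D = 0.04, alpha0 = a0, seed = round(100 * a0))
    f <- fitMSDPowerLaw(ensembleMSD(g$truth, maxLag = 10), fitLags = 1:10)
    expect_lt(abs(f@alpha - a0), 0.1)
  }
})

test_that("motion classes follow the exponent thresholds, boundaries
           upward", {
  expect_equal(classifyMotion(c(1.06, 0.14, 0.66)),
               c("diffusive", "immobile", "subdiffusive"))
  expect_equal(classifyMotion(c(0.3, 0.9, 1.3)),
               c("subdiffusive", "diffusive", "superdiffusive"))
})

test_that("two planted motion populations are recovered by
           embedding + density clustering", {
  gi <- genTrajectories("immobile", nTracks = 200, nFrames = 60,
                        sigmaLoc = 0.01, seed = 31)
  gb <- genTrajectories("brownian", nTracks = 200, nFrames = 60,
                        D = 0.2^2 / (2 * 0.827), seed = 32)
  tb <- tracks(gb$truth); tb$track_id <- tb$track_id + 1000
  ts <- new("TrackSet", tracks = rbind(tracks(gi$truth), tb), dt = 0.827)
  fe <- featureTable(ts)
  cl <- embedAndCluster(fe, seed = 1, maxIter = 500)
  truth <- ifelse(fe$track_id > 1000, "bro", "imm")
  lab <- cl$labels
  big <- setdiff(unique(lab), -1)
  expect_equal(length(setdiff(big, cl$excluded)), 2)
  # label agreement after majority matching
  agree <- sum(vapply(big, function(k) {
    max(table(truth[lab == k]))
  }, numeric(1)))
  expect_gte(agree / length(lab), 0.95)
})

test_that("clustering is deterministic and collapses duplicated rows", {
  set.seed(2)
  X <- matrix(rnorm(40 * 8), 40, 8)
  dup <- X[rep(1, 50), ] + 0  # identical rows
  lab <- dbscanCluster(dup, eps = 0.1, minPts = 5)
  expect_equal(length(unique(lab)), 1)
  fe <- data.frame(track_id = 1:40, X)
  c1 <- embedAndCluster(fe, seed = 4, maxIter = 300)
  c2 <- embedAndCluster(fe, seed = 4, maxIter = 300)
  expect_identical(c1$labels, c2$labels)
  expect_equal(c1$embedding, c2$embedding)
  expect_error(embedAndCluster(fe[1:3, ]), "minPts")
})
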