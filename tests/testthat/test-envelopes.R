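test_that("degenerate lognormal transport places children at fixed
           distance", {
  roi <- squareROI(1000)
  p1 <- sampleUniform(roi, 200, seed = 2, channel = "1")
  # keep parents away from the border so no rejection is needed
  keep <- coords(p1)[, 1] > 10 & coords(p1)[, 1] < 990 &
          coords(p1)[, 2] > 10 & coords(p1)[, 2] < 990
  p1 <- pointPattern(coords(p1)[keep, ], roi = roi, channel = "1")
  spec <- nullModelSpec("transport_lognormal", mu = log(2), sigma = 1e-8)
  set.seed(3)
  p2 <- simulateNull(p1, spec)
  d <- sqrt(rowSums((coords(p2) - coords(p1))^2))
  expect_lt(max(abs(d - 2)), 1e-6)
})

test_that("transport jump lengths follow the requested lognormal", {
  roi <- squareROI(4000)
  set.seed(4)
  p1 <- sampleUniform(roi, 5000, channel = "1")
  spec <- nullModelSpec("transport_lognormal", mu = -1.87, sigma = 0.94)
  p2 <- simulateNull(p1, spec)
  d <- sqrt(rowSums((coords(p2) - coords(p1))^2))
  ks <- suppressWarnings(stats::ks.test(d, "plnorm", -1.87, 0.94))
  expect_gt(ks$p.value, 0.01)
})

test_that("count matching appends uniform points or subsamples", {
  roi <- squareROI(50)
  p1 <- sampleUniform(roi, 10, seed = 5, channel = "1")
  set.seed(6)
  p7 <- simulateNull(p1, nullModelSpec("transport_lognormal", nM = 7))
  expect_equal(npoints(p7), 7)
  set.seed(7)
  p13 <- simulateNull(p1, nullModelSpec("transport_lognormal", nM = 13))
  expect_equal(npoints(p13), 13)
  set.seed(8)
  pc <- simulateNull(p1, nullModelSpec("csr", nM = 42))
  expect_equal(npoints(pc), 42)
})

test_that("an ROI too small for the jump scale raises an infeasible-geometry
           error", {
  tiny <- RegionOfInterest(cbind(c(0, 1e-4, 1e-4, 0), c(0, 0, 1e-4, 1e-4)))
  p1 <- pointPattern(5e-5, 5e-5, roi = tiny, channel = "1")
  spec <- nullModelSpec("transport_lognormal", mu = log(50), sigma = 1e-6)
  set.seed(1)
  expect_error(simulateNull(p1, spec, maxRedraw = 100), "infeasible")
})

test_that("envelope construction follows the per-r exclusion arithmetic", {
  r <- c(1, 2, 3)
  sims <- lapply(1:10, function(i)
    new("SummaryCurve", r = r, values = rep(i, 3), statistic = "G12",
        metadata = list()))
  dataC <- new("SummaryCurve", r = r, values = rep(5.5, 3),
               statistic = "G12", metadata = list())
  env <- buildEnvelope(dataC, sims, alpha = 0.2)
  # mean 5.5; the two most deviating values {10, 1} are excluded
  expect_equal(env@mean, rep(5.5, 3))
  expect_equal(env@lo, rep(2, 3))
  expect_equal(env@hi, rep(9, 3))
  expect_equal(env@retained, rep(8L, 3))
  env0 <- buildEnvelope(dataC, sims, alpha = 0)
  expect_equal(env0@lo, rep(1, 3))
  expect_equal(env0@hi, rep(10, 3))
  expect_error(buildEnvelope(
    new("SummaryCurve", r = c(1, 2), values = c(0, 0), statistic = "G12",
        metadata = list()), sims), "grid")
})

test_that("envelopes are nested in alpha and retain N - floor(alpha N)
           values", {
  roi <- squareROI(20)
  p1 <- sampleUniform(roi, 60, seed = 31, channel = "1")
  p2 <- sampleUniform(roi, 60, seed = 32, channel = "2")
  # K12 values are continuous, so boundary ties have probability zero
  r <- seq(1, 6, length.out = 20)
  dataC <- kFunction(p1, p2, r = r)
  sims <- lapply(1:40, function(i) {
    set.seed(100 + i)
    kFunction(p1, simulateNull(p1, nullModelSpec("csr", nM = 60)), r = r)
  })
  M <- do.call(rbind, lapply(sims, curveValues))
  for (alpha in c(0.05, 0.2)) {
    env <- buildEnvelope(dataC, sims, alpha = alpha)
    inside <- colSums(t(t(M) >= env@lo - 1e-12) &
                      t(t(M) <= env@hi + 1e-12))
    expect_equal(unname(inside), rep(40 - floor(alpha * 40), length(r)))
  }
  envA <- buildEnvelope(dataC, sims, alpha = 0.05)
  envB <- buildEnvelope(dataC, sims, alpha = 0.2)
  expect_true(all(envB@lo >= envA@lo - 1e-12))
  expect_true(all(envB@hi <= envA@hi + 1e-12))
})

test_that("rejection intervals are maximal runs outside the band", {
  r <- 1:6
  mk <- function(v) new("SummaryCurve", r = r, values = v,
                        statistic = "G12", metadata = list())
  sims <- lapply(1:20, function(i) mk(rep(c(0, 1), 3)))
  env <- buildEnvelope(mk(rep(c(0, 1), 3)), sims, alpha = 0.05)
  expect_equal(nrow(rejectionIntervals(env)), 0)
  expect_false(envelopeTest(env)$reject)
  env2 <- buildEnvelope(mk(c(0, 5, 5, 1, 0, 5)), sims, alpha = 0.05)
  iv <- rejectionIntervals(env2)
  expect_equal(unname(iv[, "r_lo"]), c(2, 6))
  expect_equal(unname(iv[, "r_hi"]), c(3, 6))
  expect_true(envelopeTest(env2)$reject)
})

test_that("runSMSS is deterministic under a fixed seed", {
  g <- genPatternPair("transport_lognormal", roi = squareROI(20), n1 = 60,
                      seed = 77)
  r <- seq(0, 3, length.out = 40)
  e1 <- runSMSS(g$p1, g$p2, "G12", nullModelSpec("csr"), nsim = 20,
                seed = 5, r = r)
  e2 <- runSMSS(g$p1, g$p2, "G12", nullModelSpec("csr"), nsim = 20,
                seed = 5, r = r)
  expect_identical(e1@lo, e2@lo)
  expect_identical(e1@hi, e2@hi)
  expect_identical(e1@data, e2@data)
  expect_identical(rejectionIntervals(e1), rejectionIntervals(e2))
})

test_that("pointwise coverage under the CSR null is near nominal", {
  roi <- squareROI(20)
  set.seed(55)
  rFix <- 1.5
  hits <- vapply(1:60, function(i) {
    p1 <- sampleUniform(roi, 40, channel = "1")
    p2 <- sampleUniform(roi, 40, channel = "2")
    env <- runSMSS(p1, p2, "G12", nullModelSpec("csr"), nsim = 50,
                   seed = 1000 + i, r = rFix)
    env@data >= env@lo & env@data <= env@hi
  }, logical(1))
  # expect roughly 95% coverage at a fixed r; allow a generous binomial band
  expect_gt(mean(hits), 0.85)
})
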