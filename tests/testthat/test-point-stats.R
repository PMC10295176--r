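test_that("G12 step function matches hand-computed NN distances", {
  sq <- squareROI(20)
  p1 <- pointPattern(c(0, 10), c(0, 0), roi = sq, channel = "1")
  p2 <- pointPattern(1, 0, roi = sq, channel = "2")
  r <- c(0.5, 1, 5, 9, 12)
  expect_equal(curveValues(nnFunction(p1, p2, r = r)),
               c(0, 0.5, 0.5, 1, 1))
  # identical patterns: every NN distance is zero
  p <- sampleUniform(sq, 20, seed = 1)
  pa <- pointPattern(coords(p), roi = sq, channel = "1")
  pb <- pointPattern(coords(p), roi = sq, channel = "2")
  expect_equal(curveValues(nnFunction(pa, pb, r = c(0, 1))), c(1, 1))
})

test_that("empty patterns raise an explicit error", {
  sq <- squareROI(20)
  p1 <- pointPattern(numeric(0), numeric(0), roi = sq)
  p2 <- pointPattern(1, 1, roi = sq, channel = "2")
  expect_error(nnFunction(p1, p2, r = 1), "empty")
  expect_error(kFunction(p2, p1, r = 1), "empty")
})

test_that("translation-corrected K12 reproduces the worked single-pair
           value", {
  sq <- squareROI(10)
  p1 <- pointPattern(2, 2, roi = sq, channel = "1")
  p2 <- pointPattern(2, 4, roi = sq, channel = "2")
  expect_equal(curveValues(kFunction(p1, p2, r = 3)), 125)
  expect_equal(curveValues(kFunction(p1, p2, r = 1.9)), 0)
})

test_that("G12 and K12 match brute-force enumeration on small patterns", {
  set.seed(23)
  for (rep in 1:8) {
    W <- runif(1, 5, 15); H <- runif(1, 5, 15)
    roi <- squareROI(W, H)
    n1 <- sample(1:10, 1); n2 <- sample(1:10, 1)
    if (n1 + n2 > 20) next
    p1 <- sampleUniform(roi, n1, channel = "1")
    p2 <- sampleUniform(roi, n2, channel = "2")
    r <- seq(0.2, sqrt(W^2 + H^2), length.out = 25)
    expect_equal(curveValues(nnFunction(p1, p2, r = r)),
                 bfG12(coords(p1), coords(p2), r), tolerance = 1e-12)
    expect_equal(curveValues(kFunction(p1, p2, r = r)),
                 bfK12rect(coords(p1), coords(p2), r, W, H),
                 tolerance = 1e-12)
  }
})

test_that("the rectangle fast path agrees with general polygon clipping", {
  # same geometry, one rectangle written as a redundant 5-gon to force the
  # exact-clipping code path
  rect <- squareROI(12, 8)
  poly <- RegionOfInterest(cbind(c(0, 6, 12, 12, 0), c(0, 0, 0, 8, 8)))
  p1 <- sampleUniform(rect, 15, seed = 3, channel = "1")
  p2 <- sampleUniform(rect, 15, seed = 4, channel = "2")
  q1 <- pointPattern(coords(p1), roi = poly, channel = "1")
  q2 <- pointPattern(coords(p2), roi = poly, channel = "2")
  r <- seq(0.5, 4, length.out = 15)
  expect_equal(curveValues(kFunction(p1, p2, r = r)),
               curveValues(kFunction(q1, q2, r = r)), tolerance = 1e-9)
})

test_that("summary functions are monotone and bounded where required", {
  roi <- defaultCellROI()
  p1 <- sampleUniform(roi, 80, seed = 5, channel = "1")
  p2 <- sampleUniform(roi, 90, seed = 6, channel = "2")
  r <- seq(0, 8, length.out = 60)
  G <- curveValues(nnFunction(p1, p2, r = r))
  expect_true(all(G >= 0 & G <= 1))
  expect_true(all(diff(G) >= 0))
  K <- curveValues(kFunction(p1, p2, r = r))
  expect_true(all(K >= 0))
  expect_true(all(diff(K) >= -1e-12))
})

test_that("K12 is exchange-symmetric under translation correction", {
  roi <- defaultCellROI()
  p1 <- sampleUniform(roi, 40, seed = 8, channel = "1")
  p2 <- sampleUniform(roi, 55, seed = 9, channel = "2")
  r <- seq(0.5, 6, length.out = 20)
  expect_equal(curveValues(kFunction(p1, p2, r = r)),
               curveValues(kFunction(p2, p1, r = r)), tolerance = 1e-10)
})

test_that("g12 integrates back to the K-function derivative", {
  sq <- squareROI(50)
  set.seed(77)
  p1 <- sampleUniform(sq, 400, channel = "1")
  p2 <- sampleUniform(sq, 400, channel = "2")
  h <- 0.3
  r <- seq(1, 8, by = 0.05)
  g <- curveValues(pairCorrelation(p1, p2, r = r, bandwidth = h))
  K <- curveValues(kFunction(p1, p2, r = r))
  dKdr <- c(NA, diff(K) / diff(r))
  gFromK <- dKdr / (2 * pi * r)
  # compare smoothed finite differences against the kernel estimate
  ok <- is.finite(gFromK)
  expect_lt(abs(mean(g[ok]) - mean(gFromK[ok])), 0.05)
})

test_that("g12 rejects invalid grids and bandwidths", {
  sq <- squareROI(10)
  p1 <- pointPattern(2, 2, roi = sq); p2 <- pointPattern(3, 3, roi = sq, channel = "2")
  expect_error(pairCorrelation(p1, p2, r = c(0, 1)), "exclude r = 0")
  expect_error(pairCorrelation(p1, p2, r = 1, bandwidth = -1), "bandwidth")
})

test_that("patterns on different ROIs are refused", {
  p1 <- pointPattern(0.5, 0.5, roi = unitSquare())
  p2 <- pointPattern(1, 1, roi = squareROI(10), channel = "2")
  expect_error(nnFunction(p1, p2, r = 1), "share one ROI")
})
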