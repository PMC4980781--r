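test_that("empirical CDF matches a direct counting oracle", {
  ## point mass
  cdf <- empiricalCDF(rep(10, 50), 256L, c(0, 255))
  expect_true(all(cdf$cdf[cdf$binEdges[-1L] < 10] == 0))
  expect_true(all(cdf$cdf[cdf$binEdges[-257L] >= 10] == 1))
  ## symmetric two-point mass
  cdf2 <- empiricalCDF(c(rep(0, 500), rep(255, 500)), 256L, c(0, 255))
  expect_equal(cdf2$cdf[1L], 0.5)
  expect_equal(cdf2$cdf[256L], 1)
  ## seeded uniform pixels vs counting at every bin edge
  set.seed(11)
  px <- runif(1000, 0, 255)
  cdf3 <- empiricalCDF(px, 256L, c(0, 255))
  counted <- vapply(cdf3$binEdges[-1L], function(e) mean(px <= e),
                    numeric(1))
  expect_lt(max(abs(cdf3$cdf - counted)), 1e-12)
  expect_error(empiricalCDF(numeric(0)), "empty")
  expect_error(empiricalCDF(1:5, range = c(2, 2)), "degenerate")
})

test_that("learned model records the pooled CDF at the reference", {
  set.seed(4)
  fr <- lapply(1:3, function(i) matrix(runif(400, 0, 100), 20))
  s <- frameSequence(fr)
  ## 30% of pixels at/below the 0.3 quantile
  iref <- unname(quantile(unlist(fr), 0.3))
  m <- learnStandardization(s, iRefValue = iref)
  expect_lt(abs(m@fRef - 0.3), 1 / 256 + 1e-3)
  mTop <- learnStandardization(s, iRefValue = globalRange(s)[2L])
  expect_equal(mTop@fRef, 1)
  expect_error(learnStandardization(s, iRefValue = -5), "outside")
})

test_that("iTest matching minimizes |F - fRef| with smallest-intensity ties", {
  ## single step CDF: everything at intensity 10, so the only candidate
  ## bin is the one holding the step
  cdf <- empiricalCDF(rep(10, 99), 256L, c(0, 255))
  step <- findInterval(10, cdf$binEdges, left.open = TRUE)
  expect_equal(findITest(cdf, 0.5), cdf$binMids[step])
  ## fRef = 0 on a CDF that is zero up to 40: the lowest occupied bin wins
  cdf2 <- empiricalCDF(c(rep(40, 10), rep(200, 10)), 256L, c(0, 255))
  expect_equal(findITest(cdf2, 0),
               cdf2$binMids[findInterval(40, cdf2$binEdges,
                                         left.open = TRUE)])
  ## random CDF vs exhaustive scan over occupied bins
  set.seed(21)
  cdf3 <- empiricalCDF(runif(500, 0, 255), 256L, c(0, 255))
  d <- abs(cdf3$cdf - 0.7)
  d[diff(c(0, cdf3$cdf)) <= 0] <- Inf
  expect_equal(findITest(cdf3, 0.7), cdf3$binMids[which(d == min(d))[1L]])
})

test_that("window standardization applies T1 then T2 literally", {
  ## hand-checked point: gMin = lMin = 0, gMax = 255, iTest = 50,
  ## iRef = 100: pixel 50 -> T1 = 100 -> T2 = 100
  m <- new("StandardizationModel", iRef = 100, fRef = 0.5, gMin = 0,
           gMax = 255, nBins = 256L, cdf = list())
  tr <- new("FrameTriplet",
            prev = matrix(50, 5, 5), center = matrix(50, 5, 5),
            nxt = matrix(50, 5, 5),
            paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 1L)
  ## all pixels at 50 with lMin = gMin = 0: iTest is the bin holding 50,
  ## and T1 maps 50 to (iRef/iTest)*50 = ~100, which T2 leaves at ~100
  out <- standardizeTriplet(tr, m, lminMode = "global")
  expect_true(abs(out$iTest - 50) <= (255 / 256) / 2 + 1e-9)
  scale50 <- out$triplet@center[1, 1]
  t1 <- (100 - 0) / (out$iTest - 0) * (50 - 0) + 0
  expect_equal(scale50, 255 * t1 / 255)
  expect_equal(scale50, 100, tolerance = 0.01)
  ## pixel at gMin is a fixed point of T1 and the lower anchor of T2
  tr2 <- new("FrameTriplet",
             prev = matrix(50, 5, 5), center = matrix(50, 5, 5),
             nxt = matrix(c(50, 0, rep(50, 23)), 5, 5),
             paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 1L)
  out2 <- standardizeTriplet(tr2, m, lminMode = "global")
  expect_equal(out2$triplet@nxt[2, 1], 0)
})

test_that("random windows match a direct substitution oracle pixelwise", {
  set.seed(31)
  fr <- lapply(1:5, function(i) matrix(runif(1024, 0, 255), 32))
  s <- frameSequence(fr)
  m <- learnStandardization(s)
  tr <- frameTriplet(s, 2L)
  out <- standardizeTriplet(tr, m, lminMode = "window")
  px <- c(tr@prev, tr@center, tr@nxt)
  lMin <- min(px)
  oracle <- function(I) {
    t1 <- (m@iRef - m@gMin) / (out$iTest - lMin) * (I - m@gMin) + m@gMin
    pmin(pmax(255 * (t1 - m@gMin) / (m@gMax - m@gMin), 0), 255)
  }
  expect_equal(out$triplet@center, matrix(oracle(tr@center), 32),
               tolerance = 1e-12)
  ## monotone nondecreasing in pixel intensity
  o <- order(as.vector(tr@prev))
  expect_true(all(diff(as.vector(out$triplet@prev)[o]) >= -1e-12))
})

test_that("degenerate window contrast is rejected", {
  ## construct a window whose minimum coincides with the matched bin
  ## centre: fRef = 0 matches the first bin, whose centre on [0, 255]
  ## with 256 bins is 255/512
  m <- new("StandardizationModel", iRef = 100, fRef = 0, gMin = 0,
           gMax = 255, nBins = 256L, cdf = list())
  v <- matrix(255 / 512, 4, 4)
  v2 <- v; v2[4, 4] <- 200
  tr <- new("FrameTriplet", prev = v, center = v, nxt = v2,
            paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 0L)
  expect_error(standardizeTriplet(tr, m), "degenerate window contrast")
})

test_that("standardized windows keep the background fraction at fRef", {
  ## the testable core of histogram matching: with lMin = gMin the
  ## fraction of window pixels at or below the standardized reference
  ## equals the learned cumulative probability within one bin of mass
  for (seed in 1:5) {
    set.seed(seed)
    fr <- lapply(1:4, function(i)
      matrix(rgamma(900, shape = 2, scale = 20) + i, 30))
    s <- frameSequence(fr)
    m <- learnStandardization(s)
    std <- standardizeTriplet(frameTriplet(s, 1L), m, lminMode = "global")
    px <- c(std$triplet@prev, std$triplet@center, std$triplet@nxt)
    frac <- mean(px <= std$tRef)
    wcdf <- empiricalCDF(c(frameAt(s, 1L), frameAt(s, 2L), frameAt(s, 3L)),
                         m@nBins, globalRange(s))
    binMass <- max(diff(c(0, wcdf$cdf)))
    expect_lt(abs(frac - m@fRef), binMass + 1e-9)
  }
})
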