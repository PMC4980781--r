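test_that("diffusivity forms match their closed forms", {
  expect_equal(diffusivity(0, 7), 1)
  expect_equal(diffusivity(0, 7, "exponential"), 1)
  expect_equal(diffusivity(10, 10), 0.5)
  expect_equal(diffusivity(10, 10, "exponential"), exp(-1))
  ## strictly decreasing
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(diffusivity(x, 5)) < 0))
  expect_error(diffusivity(1, -1), "positive")
  expect_error(diffusionParams(lambdaS = 0.3), "stability")
})

test_that("constant triplets are exact fixed points", {
  tr <- new("FrameTriplet", prev = matrix(7, 8, 8), center = matrix(7, 8, 8),
            nxt = matrix(7, 8, 8), paddedPrev = FALSE, paddedNext = FALSE,
            frameIndex = 1L)
  out <- diffuseTriplet(tr, diffusionParams(nIter = 5L))
  expect_identical(out@center, tr@center)
  expect_identical(out@prev, tr@prev)
})

test_that("identical frames reduce to frame-wise spatial diffusion", {
  set.seed(9)
  f <- matrix(runif(256, 0, 255), 16)
  tr <- new("FrameTriplet", prev = f, center = f, nxt = f,
            paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 1L)
  out <- diffuseTriplet(tr, diffusionParams(nIter = 3L, tsRatio = 1))
  ## PF = NF = 0 throughout, so temporal terms vanish and all three frames
  ## evolve identically under the spatial scheme
  expect_equal(out@prev, out@center, tolerance = 1e-14)
  expect_equal(out@nxt, out@center, tolerance = 1e-14)
  noTemporal <- diffuseTriplet(tr, diffusionParams(nIter = 3L, tsRatio = 0))
  expect_equal(out@center, noTemporal@center, tolerance = 1e-14)
})

test_that("one explicit step equals the literal substitution oracle", {
  ## near-linear regime on a bright centre pixel
  C <- matrix(0, 5, 5); C[3, 3] <- 100
  P <- matrix(0, 5, 5); N <- matrix(0, 5, 5)
  tr <- new("FrameTriplet", prev = P, center = C, nxt = N,
            paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 1L)
  out <- diffuseTriplet(tr, diffusionParams(lambdaS = 0.2, tsRatio = 1,
                                            k = 1e6, nIter = 1L))
  orc <- oracleDiffuseStep(P, C, N, 0.2, 1, 1e6)
  expect_lt(max(abs(out@center - orc$center)), 1e-12)
  expect_lt(max(abs(out@prev - orc$prev)), 1e-12)
  expect_lt(max(abs(out@nxt - orc$nxt)), 1e-12)
  ## random triplet in the nonlinear regime, both diffusivity forms
  for (form in c("rational", "exponential")) {
    tr2 <- randomTriplet(17, c(7L, 6L))
    out2 <- diffuseTriplet(tr2, diffusionParams(lambdaS = 0.2, tsRatio = 0.5,
                                                k = 15, nIter = 1L,
                                                gForm = form))
    orc2 <- oracleDiffuseStep(tr2@prev, tr2@center, tr2@nxt, 0.2, 0.5, 15,
                              form)
    expect_lt(max(abs(out2@center - orc2$center)), 1e-12)
    expect_lt(max(abs(out2@prev - orc2$prev)), 1e-12)
    expect_lt(max(abs(out2@nxt - orc2$nxt)), 1e-12)
  }
})

test_that("discrete extremum principle holds over iterations", {
  for (seed in 1:10) {
    tr <- randomTriplet(seed, c(24L, 24L))
    hi <- max(tr@prev, tr@center, tr@nxt)
    lo <- min(tr@prev, tr@center, tr@nxt)
    for (s in 1:4) {
      tr <- diffuseTriplet(tr, diffusionParams(lambdaS = 0.2, tsRatio = 1,
                                               nIter = 1L))
      hi2 <- max(tr@prev, tr@center, tr@nxt)
      lo2 <- min(tr@prev, tr@center, tr@nxt)
      expect_lte(hi2, hi + 1e-9)
      expect_gte(lo2, lo - 1e-9)
      hi <- hi2; lo <- lo2
    }
  }
})

test_that("the linear limit approximates an isotropic Gaussian blur", {
  set.seed(5)
  f <- matrix(runif(4096, 0, 255), 64)
  tr <- new("FrameTriplet", prev = f, center = f, nxt = f,
            paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 1L)
  out <- diffuseTriplet(tr, diffusionParams(lambdaS = 0.2, tsRatio = 0,
                                            k = 1e6, nIter = 50L))
  ## 50 explicit steps of size 0.2 carry per-axis variance 2*0.2*50 = 20
  ref <- oracleGaussBlur(f, sqrt(20))
  expect_gt(cor(as.vector(out@center), as.vector(ref)), 0.999)
})

test_that("edges survive diffusion while in-region variance collapses", {
  set.seed(13)
  f <- matrix(20, 32, 32); f[, 17:32] <- 220
  f <- f + matrix(rnorm(1024, 0, 3), 32)
  tr <- new("FrameTriplet", prev = f, center = f, nxt = f,
            paddedPrev = FALSE, paddedNext = FALSE, frameIndex = 1L)
  out <- diffuseTriplet(tr, diffusionParams(k = 15, nIter = 10L))
  crossEdge <- function(m) max(abs(m[, 17] - m[, 16]))
  expect_gt(crossEdge(out@center), 0.9 * crossEdge(f))
  inVar <- function(m) stats::var(as.vector(m[, 2:15]))
  expect_lt(inVar(out@center), 0.5 * inVar(f))
})
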