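test_that("Chan-Vese energy has its closed-form special cases", {
  ## phi sign matching a two-valued image: fitting terms vanish
  ## the arctan Heaviside has polynomial tails, so the phases are sharp
  ## only for |phi| >> epsilon
  img <- matrix(20, 12, 12) / 255; img[4:9, 4:9] <- 200 / 255
  ph <- matrix(-1e5, 12, 12); ph[4:9, 4:9] <- 1e5
  w <- cvWeights(mu = 0, nu = 0, epsilon = 0.01)
  e <- cvEnergy(ph, img, w)
  expect_equal(e$c1, 200 / 255, tolerance = 1e-3)
  expect_equal(e$c2, 20 / 255, tolerance = 1e-3)
  expect_lt(e$energy, 1e-2)
  ## constant image: both means equal the value, zero energy
  e2 <- cvEnergy(matrix(1, 8, 8), matrix(7, 8, 8), cvWeights(mu = 0))
  expect_equal(e2$c1, 7)
  expect_equal(e2$c2, 7)
  expect_equal(e2$energy, 0)
})

test_that("energy equals the double-loop summation oracle", {
  set.seed(14)
  img <- matrix(runif(256), 16)
  ph <- matrix(rnorm(256), 16)
  w <- cvWeights(mu = 0.3, nu = 0.1, lambda1 = 1.5, lambda2 = 0.7,
                 epsilon = 1.2)
  e <- cvEnergy(ph, img, w)
  orc <- oracleCVEnergy(ph, img, 0.3, 0.1, 1.5, 0.7, 1.2)
  expect_lt(abs(e$energy - orc$energy), 1e-9)
  expect_equal(e$c1, orc$c1, tolerance = 1e-12)
  expect_equal(e$c2, orc$c2, tolerance = 1e-12)
})

test_that("phase swap with equal fitting weights leaves energy unchanged", {
  set.seed(15)
  img <- matrix(runif(144), 12)
  ph <- matrix(rnorm(144), 12)
  w <- cvWeights(mu = 0, nu = 0, lambda1 = 1, lambda2 = 1, epsilon = 1e-9)
  ## with a near-sharp Heaviside, relabelling phases swaps c1/c2 only
  e1 <- cvEnergy(ph, img, w)
  e2 <- cvEnergy(-ph, img, w)
  expect_equal(e1$energy, e2$energy, tolerance = 1e-6)
  expect_equal(e1$c1, e2$c2, tolerance = 1e-6)
})

test_that("regularized Heaviside is a exact partition of unity", {
  z <- seq(-50, 50, by = 0.37)
  H <- STCellSeg:::.heaviside
  expect_equal(H(z, 1) + H(-z, 1), rep(1, length(z)), tolerance = 1e-15)
})

test_that("descent converges onto a clean disk with monotone energy", {
  d <- makeDisk(c(64L, 64L), c(32, 32), 15)
  img <- d$img / 255
  r <- matrix(1:64, 64, 64); cc <- t(r)
  phi0 <- 22 - sqrt((r - 32)^2 + (cc - 32)^2)   # circle enclosing the disk
  fld <- cvEvolve(phi0, img, cvWeights())
  expect_gte(diceCoefficient(levelSetMask(fld), d$mask), 0.99)
  tr <- energyTrace(fld)
  expect_true(all(diff(tr) <= pmax(abs(tr[-length(tr)]) * 1e-6, 1e-9)))
  expect_lte(iFinal(fld), cvWeights()$maxIter)
  ## degenerate flag: an all-foreground field falls back to global mean
  e <- cvEnergy(matrix(100, 8, 8), matrix(runif(64), 8), cvWeights())
  expect_true(attr(e, "degenerate"))
})

test_that("temporal linking hands the field over bit-exactly", {
  img <- makeDisk(c(32L, 32L), c(16, 16), 8)$img
  s <- frameSequence(list(img, img, img))
  res <- tcvSequence(s, w = cvWeights(maxIter = 150L))
  ## re-running frame 2 from frame 1's final field reproduces it exactly
  gr <- globalRange(s)
  scaled <- (img - gr[1L]) / (gr[2L] - gr[1L])
  manual <- cvEvolve(phi(res$fields[[1L]]), scaled, cvWeights(maxIter = 150L))
  expect_identical(phi(res$fields[[2L]]), phi(manual))
  ## identical frames give identical masks
  expect_identical(res$masks[[1L]], res$masks[[2L]])
  expect_identical(res$masks[[2L]], res$masks[[3L]])
  ## warm start converges no slower than the cold start
  cold <- cvEvolve(initialPhi(c(32L, 32L)), scaled, cvWeights(maxIter = 150L))
  expect_lte(iFinal(res$fields[[2L]]), iFinal(cold))
})

test_that("a temporally linked contour tracks a slowly moving disk", {
  frames <- lapply(0:4, function(t)
    makeDisk(c(48L, 48L), c(14 + 2 * t, 24), 9)$img)
  gt <- lapply(0:4, function(t)
    makeDisk(c(48L, 48L), c(14 + 2 * t, 24), 9)$mask)
  s <- frameSequence(frames)
  res <- tcvSequence(s, phiInit = maskToPhi(gt[[1L]], TRUE),
                     w = cvWeights(maxIter = 200L))
  for (t in 1:5)
    expect_gte(diceCoefficient(res$masks[[t]] > 0, gt[[t]]), 0.95)
})
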