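test_that("watershed partitions the frame from regional minima", {
  ## constant map: one region covering everything
  lab <- watershedRegions(matrix(0.5, 16, 16))
  expect_equal(attr(lab, "nRegions"), 1L)
  expect_true(all(lab == 1L))
  ## two parabolic pits separated by a ridge: two basins split at the ridge
  r <- matrix(1:32, 32, 32); cc <- t(r)
  pit1 <- ((r - 8)^2 + (cc - 16)^2) / 400
  pit2 <- ((r - 24)^2 + (cc - 16)^2) / 400
  surf <- pmin(pit1, pit2, 1)
  lab2 <- watershedRegions(surf)
  expect_equal(attr(lab2, "nRegions"), 2L)
  expect_false(lab2[8, 16] == lab2[24, 16])
  ## the boundary lies on the equidistant ridge row 16
  expect_true(all(lab2[1:15, ] == lab2[8, 16]))
  expect_true(all(lab2[17:32, ] == lab2[24, 16]))
  ## partition contract on arbitrary input
  set.seed(3)
  lab3 <- watershedRegions(matrix(runif(400), 20))
  expect_true(all(lab3 >= 1L))
  expect_setequal(unique(as.vector(lab3)), seq_len(attr(lab3, "nRegions")))
})

test_that("regions classify by mean intensity against the reference", {
  lab <- matrix(1L, 10, 10); lab[, 6:10] <- 2L
  attr(lab, "nRegions") <- 2L
  frame <- matrix(200, 10, 10); frame[, 6:10] <- 5
  mdl <- regionModel(tRef = 50)
  out <- classifyRegions(lab, frame, mdl)
  expect_true(all(out[, 1:5] == 1L))
  expect_true(all(out[, 6:10] == 0L))
  ## adjacent foreground regions merge into a single instance
  frame2 <- matrix(200, 10, 10); frame2[, 6:10] <- 180
  out2 <- classifyRegions(lab, frame2, mdl)
  expect_equal(max(out2), 1L)
  expect_true(all(out2 == 1L))
})

test_that("the likelihood filter vetoes implausible areas", {
  ## 1-pixel region of high intensity: area z-score under the cell model
  ## is (1-200)/50 ~ -4, so the region is demoted to background
  lab <- matrix(1L, 12, 12); lab[6, 6] <- 2L
  frame <- matrix(10, 12, 12); frame[6, 6] <- 250
  mdl <- regionModel(tRef = 50, areaMean = c(NA, 200), areaSd = c(NA, 50),
                     useLikelihoods = TRUE)
  out <- classifyRegions(lab, frame, mdl)
  expect_equal(max(out), 0L)
  ## same region with a plausible area model is kept
  mdl2 <- regionModel(tRef = 50, areaMean = c(NA, 1), areaSd = c(NA, 2),
                      useLikelihoods = TRUE)
  out2 <- classifyRegions(lab, frame, mdl2)
  expect_equal(max(out2), 1L)
})

test_that("foreground shrinks monotonically as the threshold rises", {
  set.seed(6)
  f <- matrix(runif(900, 0, 255), 30)
  em <- edgeIndexMap(f, h = 10, window = 5L)
  lab <- watershedRegions(em)
  sizes <- vapply(c(20, 60, 120, 200), function(tr) {
    sum(classifyRegions(lab, f, regionModel(tRef = tr)) > 0L)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("clean two-blob frames delineate into two accurate instances", {
  ## noiseless pair of separated nuclei pushed through the full
  ## edge-map -> watershed -> classification chain
  sim <- generateSequence(simConfig(dims = c(96L, 96L), nFrames = 3L,
                                    nCells = 2L, amplitude = 200,
                                    background = 20, minSeparation = 10,
                                    radiusRange = c(10, 13),
                                    noiseSd = 1, seed = 12L))
  f <- frameAt(sim$sequence, 2L)
  gt <- sim$masks[[2L]]
  em <- edgeIndexMap(f, h = 8, window = 7L)
  lab <- watershedRegions(em)
  ## threshold at the half-maximum level, the ground-truth support rule
  out <- classifyRegions(lab, f, regionModel(tRef = 20 + 100))
  expect_equal(max(out), 2L)
  for (inst in 1:2) {
    gtInst <- gt == inst
    ## match the predicted instance with the larger overlap
    best <- which.max(vapply(1:2, function(p)
      sum(out == p & gtInst), numeric(1)))
    expect_gte(diceCoefficient(out == best, gtInst), 0.9)
  }
  ## instance count never exceeds the foreground watershed-region count
  fgRegions <- unique(lab[out > 0L])
  expect_lte(max(out), length(fgRegions))
})
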