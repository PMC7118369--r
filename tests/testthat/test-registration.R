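test_that("pearsonOverlap is exact on the positive-overlap mask", {
  a <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, byrow = TRUE)
  b <- matrix(c(2, 1, 4, 3, 6, 5, 8, 7, 9), 3, byrow = TRUE)
  expect_equal(pearsonOverlap(a, b, minOverlap = 4), oraclePearson(a, b),
               tolerance = 1e-12)
  # self-correlation and affine invariance on the mask
  expect_equal(pearsonOverlap(a, a, minOverlap = 4), 1)
  expect_equal(pearsonOverlap(a, 2 * a, minOverlap = 4), 1)
  expect_equal(pearsonOverlap(a, 3 * a + 7, minOverlap = 4), 1)
  # only mutually positive pixels enter the mask
  az <- a; az[1, 1] <- 0
  bz <- b; bz[3, 3] <- 0
  keep <- az > 0 & bz > 0
  expect_equal(pearsonOverlap(az, bz, minOverlap = 4),
               oraclePearson(az, bz), tolerance = 1e-12)
  expect_equal(sum(keep), 7)
})

test_that("pearsonOverlap separates dimension mismatch from degenerate overlap", {
  a <- matrix(1:9, 3)
  expect_error(pearsonOverlap(a, matrix(1:16, 4)), "dimensions")
  # too-small mask
  expect_error(pearsonOverlap(a, a, minOverlap = 64), class = "ivq_degenerate_overlap")
  # zero variance on the mask
  expect_error(pearsonOverlap(matrix(5, 3, 3), a, minOverlap = 4),
               class = "ivq_degenerate_overlap")
})

test_that("shiftFrame translates with zero fill and leaves the input unmodified", {
  m <- matrix(as.numeric(1:16), 4, 4)
  expect_identical(shiftFrame(m, 0, 0), m)
  # ramp shifted one column right: column 1 zero, column j = original j-1
  s <- shiftFrame(m, 1, 0)
  expect_true(all(s[, 1] == 0))
  expect_equal(s[, 2:4], m[, 1:3])
  expect_equal(s, oracleShift(m, 1, 0))
  # inverse composition restores never-vacated interior pixels
  rt <- shiftFrame(shiftFrame(m, 3, -2), -3, 2)
  expect_equal(rt[3:4, 1], m[3:4, 1])
  expect_equal(m, matrix(as.numeric(1:16), 4, 4))   # input untouched
  expect_error(shiftFrame(m, 4, 0), "magnitude")
  # general agreement with the independent oracle
  for (s in list(c(2, 1), c(-1, 3), c(0, -2))) {
    expect_equal(shiftFrame(m, s[1], s[2]), oracleShift(m, s[1], s[2]))
  }
})

test_that("greedyAlign finds the global optimum on unimodal surfaces", {
  ref <- blobImage(48, rowC = 24, colC = 22)
  expect_identical(greedyAlign(ref, ref)$shift, c(0L, 0L))
  expect_true(greedyAlign(ref, ref)$converged)
  # known translation: greedy result equals the exhaustive-search oracle
  moving <- oracleShift(ref, 3, -2)
  res <- greedyAlign(ref, moving)
  expect_identical(res$shift, c(-3L, 2L))
  expect_identical(res$shift, as.integer(oracleExhaustiveAlign(ref, moving, 10)$shift))
  # seeded positive texture translated (5, 0)
  tex <- textureImage(48, seed = 3)
  res2 <- greedyAlign(tex, oracleShift(tex, 5, 0))
  expect_identical(res2$shift, c(-5L, 0L))
  # accepted correlation sequence is strictly increasing
  expect_true(all(diff(res$rTrace) > 0))
  expect_true(all(diff(res2$rTrace) > 0))
})

test_that("greedyAlign matches exhaustive search across random blob displacements", {
  set.seed(11)
  for (i in 1:10) {
    ref <- blobImage(48, rowC = sample(18:30, 1), colC = sample(18:30, 1),
                     sigma = runif(1, 3, 5))
    dx <- sample(-8:8, 1); dy <- sample(-8:8, 1)
    moving <- oracleShift(ref, dx, dy)
    res <- greedyAlign(ref, moving)
    orc <- oracleExhaustiveAlign(ref, moving, 10)
    expect_identical(res$shift, as.integer(orc$shift))
    expect_identical(res$shift, c(-dx, -dy))
  }
})

test_that("registerMovie recovers known drift and is idempotent and replayable", {
  driftMat <- rbind(c(0, 0), c(3, -2), c(5, 1), c(-2, 4), c(1, -3))
  cfg <- staticConfig(drift = list(model = "fixed", shifts = driftMat), seed = 5)
  sim <- simulateMovie(cfg)
  res <- registerMovie(sim$movie)
  expect_equal(unname(shifts(res$shifts)), unname(-driftMat))
  expect_true(all(converged(res$shifts)))
  # zero-drift movie: all shifts stay (0, 0)
  sim0 <- simulateMovie(staticConfig(seed = 5))
  res0 <- registerMovie(sim0$movie)
  expect_true(all(shifts(res0$shifts) == 0L))
  # idempotence: registering the corrected movie finds nothing to correct
  res2 <- registerMovie(res$movie)
  expect_true(all(shifts(res2$shifts) == 0L))
  # round trip: corrected stack equals raw stack re-shifted by the ShiftSeries
  replay <- applyShifts(sim$movie, res$shifts)
  expect_identical(getChannel(replay, "rfp"), getChannel(res$movie, "rfp"))
  expect_identical(getChannel(replay, "gfp"), getChannel(res$movie, "gfp"))
})

test_that("validateCorrection applies the half-diameter success rule strictly", {
  still <- list(matrix(c(10, 10, 10, 10, 10, 20, 20, 20, 20, 20), 5))
  v <- validateCorrection(still, cellDiameterUm = 15, frameIntervalH = 1)
  expect_true(v$success)
  expect_equal(v$maxResidualUm, 0)
  # one landmark moving 0.6 diameters net over the window fails
  drift <- cbind(seq(0, 0.6 * 15, length.out = 5), rep(0, 5))
  v2 <- validateCorrection(list(still[[1]], still[[1]] + drift),
                           cellDiameterUm = 15, frameIntervalH = 1)
  expect_false(v2$success)
  expect_equal(v2$maxResidualUm, 9)
  # exactly half a diameter is not a success (movement must be less)
  half <- cbind(seq(0, 7.5, length.out = 5), rep(0, 5))
  v3 <- validateCorrection(list(still[[1]] + half), 15, 1)
  expect_false(v3$success)
  expect_error(validateCorrection(list(), 15, 1), "landmarks")
  short <- list(matrix(1:6, 3))
  expect_error(validateCorrection(short, 15, 1), "window")
})
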