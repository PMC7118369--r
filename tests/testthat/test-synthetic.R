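test_that("empty and static configurations render as specified", {
  # no cells, no noise: every frame is flat background, trajectories empty
  cfg0 <- simConfig(nStaticCells = 0L, nMigratoryCells = 0L,
                    nClusterEvents = 0L, noiseSd = 0,
                    drift = list(model = "none"), seed = 2)
  sim0 <- simulateMovie(cfg0)
  expect_equal(nrow(sim0$truth$trajectories), 0)
  rfp <- getChannel(sim0$movie, "rfp")
  expect_true(all(rfp == rfp[1, 1, 1]))
  # static cells, zero drift, no noise, no jitter: centroids frozen in time
  cfg <- staticConfig(nCells = 5L, seed = 3)
  sim <- simulateMovie(cfg)
  tr <- sim$truth$trajectories
  for (ci in unique(tr$cell_id)) {
    p <- tr[tr$cell_id == ci, c("x_um", "y_um")]
    expect_equal(max(dist(p)), 0)
  }
  # rendered content identical across frames
  expect_equal(getChannel(sim$movie, "rfp", 1), getChannel(sim$movie, "rfp", 5))
})

test_that("blob count above half-max matches the flood-fill oracle", {
  cfg <- staticConfig(nCells = 8L, seed = 1)
  sim <- simulateMovie(cfg)
  for (t in seq_len(nFrames(sim$movie))) {
    fr <- getChannel(sim$movie, "rfp", t)
    mask <- fr > (max(fr) + min(fr)) / 2
    expect_equal(oracleFloodFillCount(mask), 8)
  }
})

test_that("generation is deterministic and conserves counts and bit depth", {
  cfg <- simConfig(seed = 42)
  a <- simulateMovie(cfg)
  b <- simulateMovie(simConfig(seed = 42))
  expect_identical(getChannel(a$movie, "rfp"), getChannel(b$movie, "rfp"))
  expect_identical(getChannel(a$movie, "gfp"), getChannel(b$movie, "gfp"))
  expect_identical(a$truth$trajectories, b$truth$trajectories)
  nCells <- cfg$nStaticCells + cfg$nMigratoryCells + 2L * cfg$nClusterEvents
  expect_equal(length(unique(a$truth$trajectories$cell_id)), nCells)
  expect_equal(length(a$truth$lgr5), nCells)
  expect_true(max(getChannel(a$movie, "rfp"), getChannel(a$movie, "gfp")) <= 4095)
  expect_true(min(getChannel(a$movie, "rfp"), getChannel(a$movie, "gfp")) >= 0)
  # cluster events involve exactly two cells each
  expect_true(all(table(a$truth$clusterId[!is.na(a$truth$clusterId)]) == 2))
  # frame-0 drift is zero and trajectories span all frames
  expect_equal(a$truth$shiftsPx[1, ], c(0L, 0L))
  expect_true(all(table(a$truth$trajectories$cell_id) == cfg$nFrames))
})

test_that("noiseless drifted frames equal frame 1 translated by the true drift", {
  driftMat <- rbind(c(0, 0), c(4, -3), c(-2, 2), c(6, 1), c(-1, -5))
  cfg <- staticConfig(nCells = 6L, seed = 9,
                      drift = list(model = "fixed", shifts = driftMat))
  sim <- simulateMovie(cfg)
  f1 <- getChannel(sim$movie, "rfp", 1)
  bg <- sim$truth$config$background[["rfp"]]
  for (t in 2:5) {
    ft <- getChannel(sim$movie, "rfp", t)
    moved <- oracleShift(f1, driftMat[t, 1], driftMat[t, 2])
    inFrame <- moved > 0   # pixels carried over from frame 1
    # content that entered from outside the original frame differs only by
    # background, so compare where frame 1 content is available
    expect_equal(ft[inFrame], moved[inFrame], tolerance = 0)
    expect_true(all(ft[!inFrame] >= bg))
  }
})

test_that("excess drift triggers the out-of-frame warning and log entry", {
  driftMat <- rbind(c(0, 0), c(120, 120), c(0, 0), c(0, 0), c(0, 0))
  cfg <- staticConfig(nCells = 2L, seed = 4,
                      drift = list(model = "fixed", shifts = driftMat))
  expect_warning(sim <- simulateMovie(cfg), "50%")
  expect_match(attr(sim, "log"), "out of frame")
})

test_that("impossible placements raise a configuration error", {
  cfg <- simConfig(imageHeightPx = 36L, imageWidthPx = 36L,
                   nStaticCells = 30L, nMigratoryCells = 0L,
                   nClusterEvents = 0L, seed = 1)
  expect_error(simulateMovie(cfg), "place|margins")
})

test_that("lesion tables follow the step composition rule", {
  expect_equal(nrow(simulateLesionTable(0, seed = 1)$lesions), 0)
  expect_error(simulateLesionTable(-1), ">= 0")
  # all diameters above the threshold: every lesion contains Lgr5+ cells
  above <- simulateLesionTable(200, diameterRangeUm = c(100, 300),
                               thresholdUm = 80, seed = 2)
  expect_true(all(above$lesions$contains_lgr5))
  # single-cell-scale lesions are always Lgr5-negative
  tiny <- simulateLesionTable(200, diameterRangeUm = c(5, 14),
                              thresholdUm = 80, p0Below = 1,
                              cellDiameterMeanUm = 15, seed = 3)
  expect_false(any(tiny$lesions$contains_lgr5))
  # below-threshold positivity rate within 3 binomial SE of p0
  tab <- simulateLesionTable(1000, diameterRangeUm = c(10, 300),
                             thresholdUm = 80, p0Below = 0.4, seed = 3)
  les <- tab$lesions
  below <- les$diameter_um <= 80 & les$diameter_um > 15
  pHat <- mean(les$contains_lgr5[below])
  se <- sqrt(0.4 * 0.6 / sum(below))
  expect_lt(abs(pHat - 0.4), 3 * se)
  # deterministic given the seed
  tab2 <- simulateLesionTable(1000, diameterRangeUm = c(10, 300),
                              thresholdUm = 80, p0Below = 0.4, seed = 3)
  expect_identical(tab$lesions, tab2$lesions)
})
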