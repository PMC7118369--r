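test_that("track metrics follow the geometry of the path", {
  # static track: zero displacement, path and velocity
  m <- computeTrackMetrics(lineTrack(0), frameIntervalH = 1)
  expect_equal(m$net_displacement_um, 0)
  expect_equal(m$path_length_um, 0)
  expect_equal(m$velocity_um_per_h, 0)
  expect_false(m$migratory)
  # straight line at 10 um per 1-h frame over 4 h
  m2 <- computeTrackMetrics(lineTrack(10), frameIntervalH = 1)
  expect_equal(m2$net_displacement_um, 40)
  expect_equal(m2$path_length_um, 40)
  expect_equal(m2$velocity_um_per_h, 10)
  # square path returning to start: displacement 0, path 40
  sq <- data.frame(track_id = 1L, frame = 1:5,
                   x_um = c(0, 10, 10, 0, 0), y_um = c(0, 0, 10, 10, 0),
                   diameter_um = 20, lgr5 = TRUE)
  m3 <- computeTrackMetrics(sq, frameIntervalH = 1)
  expect_equal(m3$net_displacement_um, 0)
  expect_equal(m3$path_length_um, 40)
  # path >= net displacement always
  expect_true(all(c(m$path_length_um >= m$net_displacement_um,
                    m3$path_length_um >= m3$net_displacement_um)))
  # the "path" velocity convention divides path length by the window
  m4 <- computeTrackMetrics(sq, frameIntervalH = 1, velocityMode = "path")
  expect_equal(m4$velocity_um_per_h, 10)
})

test_that("tracks shorter than the window are excluded with a reason", {
  short <- lineTrack(10, nFrames = 3)
  m <- computeTrackMetrics(short, frameIntervalH = 1)
  expect_equal(nrow(m), 0)
  expect_match(attr(m, "excluded")$reason, "shorter")
})

test_that("the migratory boundary sits strictly above half a diameter", {
  expect_false(classifyMigratory(10, 20))     # exactly half: not migratory
  expect_true(classifyMigratory(10.1, 20))
  expect_error(classifyMigratory(5, 0), "positive")
  # monotone non-decreasing in displacement for fixed diameter
  disp <- seq(0, 20, by = 0.25)
  cls <- classifyMigratory(disp, 20)
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_equal(min(disp[cls]), 10.25)
})

test_that("mode classification separates singles from contact-maintaining pairs", {
  # a lone migratory cell is single
  solo <- lineTrack(10)
  mSolo <- classifyMode(solo, computeTrackMetrics(solo, 1), frameIntervalH = 1)
  expect_equal(mSolo$mode, "single")
  # two cells co-moving at half the summed radii are both cluster
  pair <- rbind(lineTrack(10, trackId = 1L),
                transform(lineTrack(10, trackId = 2L), y_um = y_um + 10))
  mPair <- classifyMode(pair, computeTrackMetrics(pair, 1), frameIntervalH = 1)
  expect_equal(mPair$mode, c("cluster", "cluster"))
  # a distant co-moving cell stays single
  far <- rbind(lineTrack(10, trackId = 1L),
               transform(lineTrack(10, trackId = 2L), y_um = y_um + 60))
  mFar <- classifyMode(far, computeTrackMetrics(far, 1), frameIntervalH = 1)
  expect_equal(mFar$mode, c("single", "single"))
  # modes are exclusive and exhaustive over migratory tracks
  expect_true(all(mPair$mode[mPair$migratory] %in% c("single", "cluster")))
})

test_that("synthetic cluster events and singles get the right mode labels", {
  cfg <- simConfig(nStaticCells = 2L, nMigratoryCells = 5L,
                   nClusterEvents = 3L, drift = list(model = "none"),
                   seed = 31)
  sim <- simulateMovie(cfg)
  det <- classifyLgr5(detectMovie(sim$movie))
  tracks <- linkTracks(det)
  metrics <- classifyMode(tracks, computeTrackMetrics(tracks, 1),
                          frameIntervalH = 1)
  cellOf <- matchTracksToTruth(tracks, sim$truth)
  ids <- sort(unique(tracks$track_id))
  truthMode <- sim$truth$mode[cellOf[match(metrics$track_id, ids)]]
  mig <- metrics$migratory
  expect_equal(metrics$mode[mig], truthMode[mig])
})

test_that("per-animal aggregation uses the animal as the unit of analysis", {
  mk <- function(animal, lgr5) {
    data.frame(track_id = seq_along(lgr5), migratory = TRUE,
               lgr5 = lgr5, mode = "single", animal_id = animal)
  }
  # all migratory cells Lgr5- in every animal: mean 1, SEM 0
  m <- rbind(mk("a", c(FALSE, FALSE)), mk("b", c(FALSE, FALSE, FALSE)))
  agg <- aggregateByAnimal(m)
  expect_equal(agg$group$mean[agg$group$metric == "fraction_lgr5neg"], 1)
  expect_equal(agg$group$sem[agg$group$metric == "fraction_lgr5neg"], 0)
  # two animals at 0.8 and 1.0: mean 0.9, SEM 0.1 (sd/sqrt(n) by hand)
  m2 <- rbind(mk("a", c(rep(FALSE, 4), TRUE)), mk("b", rep(FALSE, 5)))
  agg2 <- aggregateByAnimal(m2)
  expect_equal(agg2$perAnimal$fraction_lgr5neg, c(0.8, 1.0))
  expect_equal(agg2$group$mean[1], 0.9)
  expect_equal(agg2$group$sem[1], 0.1)
  # an animal with no migratory tracks is excluded, not zero-filled
  m3 <- rbind(mk("a", FALSE),
              data.frame(track_id = 9L, migratory = FALSE, lgr5 = TRUE,
                         mode = "not_migratory", animal_id = "c"))
  agg3 <- aggregateByAnimal(m3)
  expect_equal(agg3$perAnimal$animal_id, "a")
  expect_equal(attr(agg3, "excluded"), "c")
})
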