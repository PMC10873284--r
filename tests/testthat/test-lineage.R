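# toy label stacks built by hand
stackFromMats <- function(mats) simplify2array(mats)

test_that("a static mask tracks as one division-free track", {
  lab <- matrix(0L, 20, 20); lab[8:12, 5:15] <- 1L
  trk <- trackCells(stackFromMats(rep(list(lab), 5)), frame_interval = 0.5)
  expect_equal(nrow(trk$lineage), 1L)
  expect_true(is.na(trk$lineage$division_frame))
  expect_true(is.na(trk$lineage$birth_frame))
  expect_equal(nrow(trk$tracks), 5L)
  expect_equal(trk$tracks$age_h, (0:4) * 0.5)
})

test_that("a mask splitting into two halves is recorded as one division", {
  mother <- matrix(0L, 20, 24); mother[9:12, 3:20] <- 1L
  d <- matrix(0L, 20, 24); d[9:12, 3:11] <- 1L; d[9:12, 13:20] <- 2L
  trk <- trackCells(stackFromMats(list(mother, mother, d, d)),
                    frame_interval = 0.5)
  lin <- trk$lineage
  expect_equal(sum(!is.na(lin$parent)), 2L)
  expect_equal(sum(!is.na(lin$division_frame)), 1L)
  mom <- lin$track_id[is.na(lin$parent)]
  expect_equal(lin$division_frame[lin$track_id == mom], 2L)
  expect_equal(lin$birth_frame[!is.na(lin$parent)], c(2L, 2L))
})

test_that("tracks survive a single missing frame via gap closing", {
  lab <- matrix(0L, 20, 20); lab[8:12, 5:15] <- 1L
  gap <- matrix(0L, 20, 20)
  trk <- trackCells(stackFromMats(list(lab, gap, lab)), frame_interval = 0.5)
  expect_equal(nrow(trk$lineage), 1L)
  trk2 <- trackCells(stackFromMats(list(lab, gap, lab)), gap_close = FALSE)
  expect_equal(nrow(trk2$lineage), 2L)
})

test_that("generation labels follow the F0/F1/F2 definitions on a toy chain", {
  lineage <- data.frame(
    track_id = 1:7,
    parent = c(NA, 1L, 1L, 2L, 2L, NA, 4L),
    birth_frame = c(NA, 3L, 3L, 6L, 6L, NA, 9L),
    division_frame = c(3L, 6L, NA, 9L, NA, NA, NA))
  tracks <- do.call(rbind, lapply(1:7, function(t) {
    fr <- switch(t, 0:2, 3:5, 3:11, 6:8, 6:11, 0:11, 9:11)
    data.frame(track_id = t, frame = fr, cell_id = t)
  }))
  lin <- assignGenerations(lineage, tracks, n_frames = 12L)
  gen <- stats::setNames(lin$generation, lin$track_id)
  expect_equal(unname(gen["1"]), "F0")       # present at start, divided
  expect_equal(unname(gen["2"]), "F1")       # daughter of F0, divided
  expect_equal(unname(gen["4"]), "unassigned")  # daughter of F1 that divided
  expect_equal(unname(gen["5"]), "F2")       # daughter of F1, never divided
  expect_equal(unname(gen["6"]), "unassigned")  # never divided, at start
  expect_equal(unname(gen["7"]), "unassigned")  # grand-daughter
})

test_that("pole identity flags the end facing the division plane and is stable", {
  # mother along x, splitting mid-length; daughters then drift rigidly
  H <- 24L; W <- 40L
  mother <- matrix(0L, H, W); mother[11:14, 5:36] <- 1L
  f2 <- matrix(0L, H, W); f2[11:14, 5:19] <- 1L; f2[11:14, 21:36] <- 2L
  f3 <- matrix(0L, H, W); f3[12:15, 3:17] <- 1L; f3[12:15, 23:38] <- 2L
  labs <- stackFromMats(list(mother, f2, f3))
  cells <- measureStack(labs, frameStack(list(pvd = array(
    1, dim = c(H, W, 3))), 0.5, 0.1))
  trk <- trackCells(labs, cells, frame_interval = 0.5)
  poles <- poleIdentity(trk, pixel_size = 0.1)
  expect_equal(nrow(poles), 4L)   # two daughters x two frames
  # mother lay along x, so both new poles point along x
  expect_true(all(abs(poles$new_pole_y) < 0.3))
  signs <- tapply(poles$new_pole_sign, poles$cell_id, unique)
  expect_equal(length(unlist(signs)), 2L)   # identity stable across frames
  expect_true(prod(unlist(signs)) < 0)      # daughters face each other
})

test_that("elongation rate recovers the closed-form slope on exact data", {
  tracks <- data.frame(track_id = 1L, frame = 0:2, cell_id = 1L,
                       axis_length_um = c(2.0, 2.2, 2.42))
  er <- elongationRates(tracks, frame_interval = 0.5)
  expect_equal(er$rate_per_h, log(1.1) / 0.5, tolerance = 1e-10)
  # constant length: rate 0
  tracks$axis_length_um <- 3
  expect_equal(elongationRates(tracks, 0.5)$rate_per_h, 0)
  # too short
  er3 <- elongationRates(tracks[1:2, ], 0.5)
  expect_true(is.na(er3$rate_per_h))
  expect_equal(er3$flag, "too_short")
})

test_that("mean age is the arithmetic mean and newborns average zero", {
  tracks <- data.frame(track_id = 1:3, frame = 4L, cell_id = 1:3,
                       age_h = c(1, 2, 3))
  expect_equal(meanAge(tracks, 4L), 2)
  tracks$age_h <- 0
  expect_equal(meanAge(tracks, 4L), 0)
  expect_warning(ma <- meanAge(tracks, 9L), "undefined|no cells")
  expect_true(is.na(ma))
})

test_that("per-frame track presence sums to the per-frame cell count", {
  sim <- smallColony()
  cells <- measureStack(sim$labels, sim$stack)
  trk <- trackCells(sim$labels, cells, frame_interval = 0.5)
  for (f in c(0L, 10L, 23L))
    expect_equal(sum(trk$tracks$frame == f), sum(cells$frame == f))
})

test_that("mean age rises by exactly the frame interval in pure stationary phase", {
  sim <- smallColony()
  cells <- measureStack(sim$labels, sim$stack)
  trk <- trackCells(sim$labels, cells, frame_interval = 0.5)
  tc <- truthCells(sim$truth)
  statFrames <- sort(unique(tc$frame[tc$phase == "stationary"]))
  f <- statFrames[2]
  expect_equal(meanAge(trk$tracks, f) - meanAge(trk$tracks, f - 1L), 0.5)
})

test_that("tracking a noise-free colony recovers the true lineage", {
  sim <- smallColony()
  cells <- measureStack(sim$labels, sim$stack)
  trk <- trackCells(sim$labels, cells, frame_interval = 0.5)
  tl <- truthLineage(sim$truth)
  firstrow <- trk$tracks[!duplicated(trk$tracks$track_id), ]
  tid2truth <- stats::setNames(firstrow$cell_id, firstrow$track_id)
  dl <- trk$lineage[!is.na(trk$lineage$parent), ]
  predparent <- tid2truth[as.character(dl$parent)]
  trueparent <- tl$parent[match(tid2truth[as.character(dl$track_id)], tl$id)]
  expect_equal(nrow(dl), sum(!is.na(tl$parent)))
  expect_true(all(predparent == trueparent))
})
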