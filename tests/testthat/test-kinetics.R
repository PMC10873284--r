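# minimal track-result builder
toyTracks <- function(divFrame = NA_integer_, nFrames = 10L) {
  list(tracks = data.frame(track_id = 1L, frame = 0:(nFrames - 1L),
                           cell_id = 1L, age_h = (0:(nFrames - 1L)) * 0.5),
       lineage = data.frame(track_id = 1L, parent = NA_integer_,
                            birth_frame = NA_integer_,
                            division_frame = divFrame))
}

test_that("lag time is the first division frame times the interval", {
  lag <- lagTimes(toyTracks(divFrame = 6L), frame_interval = 0.5,
                  n_frames = 36L)
  expect_equal(lag$lag_h, 3.0)
  expect_false(lag$censored)
})

test_that("a never-dividing track is censored at the horizon", {
  lag <- lagTimes(toyTracks(), frame_interval = 0.5, n_frames = 36L)
  expect_true(lag$censored)
  expect_true(is.na(lag$lag_h))
  expect_equal(lag$horizon_h, 18)
})

test_that("tracks not present from frame 0 are excluded", {
  tr <- toyTracks(divFrame = 6L)
  tr$tracks$frame <- tr$tracks$frame + 2L
  tr$lineage$birth_frame <- NA_integer_
  lag <- lagTimes(tr, 0.5, 36L)
  expect_equal(nrow(lag), 0L)
})

test_that("depolarization time honours the persistence rule", {
  tr <- list(tracks = data.frame(track_id = 1L, frame = 0:4, cell_id = 1L),
             lineage = data.frame(track_id = 1L, parent = NA_integer_,
                                  birth_frame = NA_integer_,
                                  division_frame = NA_integer_))
  rec <- data.frame(cell_id = 1L, frame = 0:4,
                    label = c("polarized", "polarized", "homogeneous",
                              "homogeneous", "homogeneous"))
  dp <- depolarizationTimes(rec, tr, frame_interval = 0.5, k = 2L)
  expect_equal(dp$depol_h, 1.0)
  expect_equal(dp$flag, "ok")
  # all polarized: never depolarizes
  rec$label <- "polarized"
  dp2 <- depolarizationTimes(rec, tr, 0.5, 2L)
  expect_true(is.na(dp2$depol_h))
  expect_equal(dp2$flag, "never_depolarized")
  # not polarized at start: flagged
  rec$label <- c("homogeneous", rep("polarized", 4))
  dp3 <- depolarizationTimes(rec, tr, 0.5, 2L)
  expect_equal(dp3$flag, "not_polarized_at_start")
})

test_that("a single homogeneous flicker frame does not count as depolarization", {
  tr <- list(tracks = data.frame(track_id = 1L, frame = 0:5, cell_id = 1L),
             lineage = data.frame(track_id = 1L, parent = NA_integer_,
                                  birth_frame = NA_integer_,
                                  division_frame = NA_integer_))
  rec <- data.frame(cell_id = 1L, frame = 0:5,
                    label = c("polarized", "homogeneous", "polarized",
                              "polarized", "homogeneous", "homogeneous"))
  dp <- depolarizationTimes(rec, tr, frame_interval = 0.5, k = 2L)
  expect_equal(dp$depol_h, 2.0)
})

test_that("identical groups summarize identically and test non-significant", {
  set.seed(3)
  vals <- runif(30, 1, 5)
  recs <- rbind(
    data.frame(track_id = 1:30, condition = "a", lag_h = vals,
               censored = FALSE, horizon_h = 18),
    data.frame(track_id = 31:60, condition = "b", lag_h = vals,
               censored = FALSE, horizon_h = 18))
  cmp <- compareConditions(recs)
  expect_equal(cmp$summary$median_h[1], cmp$summary$median_h[2])
  expect_gt(cmp$tests$p_value, 0.2)
  expect_equal(cmp$tests$median_diff_h, 0)
})

test_that("quantiles use the linear interpolation convention", {
  recs <- data.frame(track_id = 1:6,
                     condition = rep(c("a", "b"), each = 3),
                     lag_h = c(1, 2, 3, 1, 2, 3),
                     censored = FALSE, horizon_h = 18)
  cmp <- suppressWarnings(compareConditions(recs, min_uncensored = 3L))
  expect_equal(cmp$summary$median_h[1], 2)
  expect_equal(cmp$summary$q25_h[1], 1.5)
  expect_equal(cmp$summary$q75_h[1], 2.5)
})

test_that("censoring bookkeeping is complete and all-censored groups skip tests", {
  recs <- rbind(
    data.frame(track_id = 1:8, condition = "a",
               lag_h = c(1, 2, 3, 4, 5, NA, NA, NA),
               censored = c(rep(FALSE, 5), rep(TRUE, 3)), horizon_h = 18),
    data.frame(track_id = 9:14, condition = "b", lag_h = NA_real_,
               censored = TRUE, horizon_h = 18))
  expect_warning(cmp <- compareConditions(recs), "too few")
  s <- cmp$summary
  expect_equal(s$n_censored + s$n_uncensored, s$n)
  expect_null(cmp$tests)
})

test_that("lag time is monotone under frame subsampling", {
  sim <- smallColony()
  cells <- measureStack(sim$labels, sim$stack)
  trk <- trackCells(sim$labels, cells, frame_interval = 0.5)
  lag1 <- lagTimes(trk, 0.5, nFrames(sim$stack))
  sub <- sim$labels[, , seq(1, dim(sim$labels)[3], by = 2)]
  cells2 <- cells[cells$frame %% 2 == 0, ]
  cells2$frame <- cells2$frame %/% 2L
  trk2 <- trackCells(sub, cells2, frame_interval = 1.0)
  lag2 <- lagTimes(trk2, 1.0, dim(sub)[3])
  m1 <- stats::median(lag1$lag_h[!lag1$censored])
  m2 <- stats::median(lag2$lag_h[!lag2$censored])
  expect_gte(m2, m1)
})
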