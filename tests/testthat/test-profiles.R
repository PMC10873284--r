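test_that("a uniform rectangle profiles flat at the uniform value", {
  m <- rectMask(3L, 18L)
  prof <- axisProfile(m$x, m$y, rep(4.5, length(m$x)), n_bins = 6L)
  expect_equal(prof$intensity, rep(4.5, 6L))
  expect_false(any(prof$interpolated))
})

test_that("an end-loaded rectangle matches the brute-force binning oracle", {
  m <- rectMask(3L, 9L)
  ints <- ifelse(m$x < 3, 2, 1)   # first axial third at 2, rest 1
  prof <- axisProfile(m$x, m$y, ints, n_bins = 3L)
  bt <- bruteThirds(m$x, m$y, ints)
  expect_equal(prof$intensity,
               unname(bt$sums / bt$counts))
  expect_equal(prof$intensity, c(2, 1, 1))
})

test_that("mirroring the mask reverses the profile", {
  set.seed(7)
  m <- rectMask(4L, 15L)
  ints <- runif(length(m$x))
  p1 <- axisProfile(m$x, m$y, ints, n_bins = 5L)
  mx <- max(m$x)
  p2 <- axisProfile(mx - m$x, m$y, ints, n_bins = 5L)
  expect_equal(p2$intensity, rev(p1$intensity))
})

test_that("degenerate axes are rejected by name", {
  expect_error(axisProfile(rep(3, 5), rep(4, 5), 1:5, cell_id = 99L), "99")
})

test_that("empty bins are interpolated and flagged", {
  # two pixel clusters far apart along the axis leave middle bins empty
  x <- c(0, 1, 14, 15); y <- c(0, 0, 0, 0)
  prof <- axisProfile(x, y, c(2, 2, 6, 6), n_bins = 5L)
  expect_true(any(prof$interpolated))
  expect_false(any(is.na(prof$intensity)))
  mid <- prof$intensity[prof$interpolated]
  expect_true(all(mid >= 2 & mid <= 6))
})

test_that("pooled profile with window 1 is the exact elementwise mean", {
  p1 <- data.frame(cell_id = 1L, frame = 0L, bin = 1:3,
                   position = c(1, 3, 5) / 6, intensity = c(1, 1, 1),
                   interpolated = FALSE)
  p2 <- p1; p2$cell_id <- 2L; p2$intensity <- c(3, 1, 1)
  pooled <- pooledProfile(rbind(p1, p2), smoothing_window = 1L)
  expect_equal(pooled$mean_intensity, c(2, 1, 1))
  expect_equal(pooled$smoothed_intensity, c(2, 1, 1))
  expect_equal(pooled$n, rep(2L, 3))
  # single profile, window 1: identity
  pooled1 <- pooledProfile(p1, smoothing_window = 1L)
  expect_equal(pooled1$mean_intensity, p1$intensity)
})

test_that("mixed n_bins are rejected when pooling", {
  p1 <- data.frame(cell_id = 1L, frame = 0L, bin = 1:3,
                   position = c(1, 3, 5) / 6, intensity = 1,
                   interpolated = FALSE)
  p2 <- data.frame(cell_id = 2L, frame = 0L, bin = 1:4,
                   position = c(1, 3, 5, 7) / 8, intensity = 1,
                   interpolated = FALSE)
  expect_error(pooledProfile(rbind(p1, p2)), "mixed")
})

test_that("profiles are invariant to rigid motion of the cell", {
  cfg <- simulationConfig(seed = 3, n_frames = 1L, n_initial = 1L,
                          shot_noise = FALSE, read_noise_sd = 0)
  base <- simulateColony(cfg)
  tc <- truthCells(base)
  tc$length_um <- 3.4
  profiles <- list()
  for (case in 1:2) {
    tt <- tc
    if (case == 2) {  # translate and rotate
      tt$cx <- tt$cx + 3.2; tt$cy <- tt$cy - 2.1
      tt$theta <- (tt$theta + 0.9) %% pi
      tt$new_pole_x <- cos(tt$theta); tt$new_pole_y <- sin(tt$theta)
    }
    tr <- base; tr@cells <- tt
    ren <- renderFrames(tr, cfg)
    cells <- measureStack(ren$labels, ren$stack)
    prof <- profileStack(ren$labels, ren$stack, cells, n_bins = 8L,
                         background = "none")
    profiles[[case]] <- prof$intensity / mean(prof$intensity)
  }
  # orientation sign of position 0 is arbitrary: compare up to reversal
  d1 <- max(abs(profiles[[1]] - profiles[[2]]))
  d2 <- max(abs(profiles[[1]] - rev(profiles[[2]])))
  expect_lt(min(d1, d2), 0.02 * mean(abs(profiles[[1]])) * 8)
})

test_that("stationary-phase pooled profile peaks at an end bin", {
  sim <- cachedSim("polarizedColony", simulationConfig(
    seed = 71, n_frames = 10L, n_initial = 40L, arrest_frame = 0L,
    polarization_onset_mean = 1.5, polarization_onset_sd = 0.75))
  cells <- measureStack(sim$labels, sim$stack)
  lastF <- max(cells$frame)
  prof <- profileStack(sim$labels, sim$stack,
                       cells[cells$frame == lastF, , drop = FALSE],
                       n_bins = 20L)
  pooled <- pooledProfile(prof, smoothing_window = 3L)
  peakBin <- which.max(pooled$smoothed_intensity)
  expect_true(peakBin <= 3L || peakBin >= 18L)
})
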