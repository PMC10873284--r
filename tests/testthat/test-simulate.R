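test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(seed = 1, birth_length = 4, division_length = 3),
               "birth_length")
  expect_error(simulationConfig(seed = 1, new_pole_bias = 1.2), "new_pole_bias")
  expect_error(simulationConfig(seed = 1, elongation_rate = -1), "negative")
  expect_error(simulationConfig(seed = 1, n_frames = 0L), "n_frames")
  expect_error(simulationConfig(seed = 1, nonsense = 2), "unknown")
  expect_error(simulationConfig(seed = 1, psf_sigma = NaN), "finite")
})

test_that("zero elongation rate means no cell ever divides", {
  truth <- simulateColony(simulationConfig(seed = 5, elongation_rate = 0,
                                           n_frames = 12L))
  expect_true(all(is.na(truthLineage(truth)$division_frame)))
  tc <- truthCells(truth)
  expect_equal(length(unique(tc$id)), simConfig(truth)@n_initial)
})

test_that("arrest at frame 0 with full new-pole bias puts every focus at the new pole", {
  truth <- simulateColony(simulationConfig(
    seed = 9, n_frames = 16L, n_initial = 20L, arrest_frame = 0L,
    new_pole_bias = 1, polarization_onset_mean = 1))
  tc <- truthCells(truth)
  pol <- tc[tc$polarized, ]
  expect_gt(nrow(pol), 0)
  expect_true(all(pol$focus_pole == "new"))
  expect_true(all(tc$phase %in% c("arrested")))
})

test_that("new-pole focus fraction matches the binomial oracle at bias 0.8", {
  truth <- simulateColony(simulationConfig(
    seed = 31, n_frames = 14L, n_initial = 220L, arrest_frame = 0L,
    new_pole_bias = 0.8, polarization_onset_mean = 2,
    polarization_onset_sd = 1))
  tc <- truthCells(truth)
  last <- tc[tc$frame == max(tc$frame) & tc$polarized, ]
  n <- nrow(last)
  expect_gte(n, 200)
  phat <- mean(last$focus_pole == "new")
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(phat - 0.8), 3 * se)
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- simulationConfig(seed = 77, n_frames = 10L, carrying_capacity = 20L)
  s1 <- simulateStack(cfg)
  s2 <- simulateStack(cfg)
  expect_identical(truthCells(s1$truth), truthCells(s2$truth))
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$stack@data, s2$stack@data)
})

test_that("colony-level invariants hold on a full simulation", {
  sim <- smallColony()
  tc <- truthCells(sim$truth)
  counts <- tapply(tc$id, tc$frame, length)
  expect_true(all(diff(counts) >= 0))  # no release event configured
  expect_false(any(tc$polarized & tc$phase == "exponential"))
  lin <- truthLineage(sim$truth)
  kids <- table(lin$parent[!is.na(lin$parent)])
  expect_true(all(kids == 2))          # lineage is a binary forest
  daughters <- lin[!is.na(lin$parent), ]
  mdiv <- lin$division_frame[match(daughters$parent, lin$id)]
  expect_equal(daughters$birth_frame, mdiv)
})

test_that("runaway growth aborts with a clear error", {
  expect_error(simulateColony(simulationConfig(
    seed = 1, n_frames = 40L, n_initial = 30L, carrying_capacity = 2L,
    lag_duration_mean = 0, lag_duration_sd = 0, elongation_rate = 2)),
    "runaway|hard limit")
})

test_that("rendered intensity conserves the ground-truth fluorophore (noise off)", {
  sim <- smallColony()
  tc <- truthCells(sim$truth)
  for (f in c(0L, 10L, 23L)) {
    tot <- sum(tc$total_fluorophore[tc$frame == f])
    img <- sum(stackFrame(sim$stack, "pvd", f + 1L))
    expect_lt(abs(img / tot - 1), 0.005)
  }
})

test_that("rendered homogeneous cells project a flat long-axis profile", {
  # focus_fraction = 0: even arrested 'polarized' cells render homogeneously
  sim <- cachedSim("flatColony", simulationConfig(
    seed = 57, n_frames = 2L, n_initial = 12L, arrest_frame = 0L,
    focus_fraction = 0, shot_noise = FALSE, read_noise_sd = 0))
  cells <- measureStack(sim$labels, sim$stack)
  prof <- profileStack(sim$labels, sim$stack, cells, n_bins = 10L,
                       background = "none")
  pooled <- pooledProfile(prof, smoothing_window = 1L)
  # outer bins keep cap geometry (fewer, rim-dominated pixels); the
  # cylindrical mid-section must read flat
  mid <- pooled$mean_intensity[3:8]
  expect_lt(max(mid) / min(mid), 1.05)
})

test_that("axial third sums match an independent direct rasterization oracle", {
  # one static cell with stated geometry and intensity
  cfg <- simulationConfig(seed = 3, n_frames = 1L, n_initial = 1L,
                          shot_noise = FALSE, read_noise_sd = 0,
                          psf_sigma = 0.1)
  truth <- simulateColony(cfg)
  tc <- truthCells(truth)
  tc$length_um <- 3.2; tc$theta <- 0.6
  tc$new_pole_x <- cos(0.6); tc$new_pole_y <- sin(0.6)
  tc$total_fluorophore <- 5000
  truth@cells <- tc
  ren <- renderFrames(truth, cfg)
  img <- stackFrame(ren$stack, "pvd", 1)
  lab <- ren$labels[, , 1]

  # independent oracle: plain-loop rasterization of the same optical model
  oracle <- directRasterOracle(tc$cx, tc$cy, tc$theta, tc$length_um,
                               cfg, 5000, dim(lab))
  idx <- which(lab == 1L)
  x <- (idx - 1L) %/% nrow(lab); y <- (idx - 1L) %% nrow(lab)
  bt <- bruteThirds(x, y, img[idx])
  bo <- bruteThirds(x, y, oracle[idx])
  expect_equal(unname(bt$sums), unname(bo$sums), tolerance = 1e-6)
})
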