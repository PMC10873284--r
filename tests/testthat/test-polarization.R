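test_that("an exact-thirds rectangle splits 9/9/9", {
  m <- rectMask(3L, 9L)
  part <- partitionThirds(m$x, m$y)
  expect_equal(length(part$pole_a), 9L)
  expect_equal(length(part$center), 9L)
  expect_equal(length(part$pole_b), 9L)
  expect_equal(sort(c(part$pole_a, part$center, part$pole_b)),
               seq_along(m$x))
})

test_that("region sizes on a 3x10 rectangle follow the half-open rule", {
  m <- rectMask(3L, 10L)
  part <- partitionThirds(m$x, m$y)
  bt <- bruteThirds(m$x, m$y, rep(1, length(m$x)))
  expect_equal(length(part$pole_a), unname(bt$counts["a"]))
  expect_equal(length(part$center), unname(bt$counts["center"]))
  expect_equal(length(part$pole_b), unname(bt$counts["b"]))
})

test_that("mirroring the mask along its axis swaps the pole pixel sets exactly", {
  # axial-coordinate denominators not divisible by 3, so no pixel sits on a
  # region boundary and the swap is exact
  for (ncols in c(9L, 11L, 15L)) {
    m <- rectMask(3L, ncols)
    part1 <- partitionThirds(m$x, m$y)
    part2 <- partitionThirds(max(m$x) - m$x, m$y)
    expect_setequal(part1$pole_a, part2$pole_b)
    expect_setequal(part1$pole_b, part2$pole_a)
    expect_setequal(part1$center, part2$center)
  }
  # an asymmetric mask, mirrored through its centre along a fixed axis
  m <- rectMask(3L, 11L)
  m$x <- c(m$x, 2L, 3L); m$y <- c(m$y, 3L, 3L)   # bump near one pole
  part1 <- partitionThirds(m$x, m$y, orientation = 0)
  part2 <- partitionThirds(max(m$x) - m$x, m$y, orientation = 0)
  expect_setequal(part1$pole_a, part2$pole_b)
  expect_setequal(part1$pole_b, part2$pole_a)
})

test_that("uniform intensity with equal regions gives ratios of exactly 1", {
  m <- rectMask(3L, 9L)
  part <- partitionThirds(m$x, m$y)
  r <- poleCenterRatio(part, rep(3, length(m$x)))
  expect_equal(unname(r), c(1, 1))
})

test_that("an end-loaded rectangle gives the closed-form ratio", {
  m <- rectMask(3L, 9L)
  ints <- ifelse(m$x < 3, 2, 1)
  part <- partitionThirds(m$x, m$y)
  r <- poleCenterRatio(part, ints)
  expect_equal(unname(r["ratio_a"]), 2.0)
  expect_equal(unname(r["ratio_b"]), 1.0)
})

test_that("ratios equal the brute-force oracle exactly on 100 random cells", {
  set.seed(2024)
  for (i in 1:100) {
    blob <- elongatedBlob(sample(30:80, 1))
    ints <- runif(length(blob$x), 0, 50)
    part <- partitionThirds(blob$x, blob$y)
    r <- poleCenterRatio(part, ints)
    bt <- bruteThirds(blob$x, blob$y, ints)
    expect_identical(unname(r["ratio_a"]),
                     unname(bt$sums["a"] / bt$sums["center"]))
    expect_identical(unname(r["ratio_b"]),
                     unname(bt$sums["b"] / bt$sums["center"]))
  }
})

test_that("ratios are scale invariant", {
  set.seed(5)
  blob <- randomBlob(50)
  ints <- runif(length(blob$x), 1, 10)
  part <- partitionThirds(blob$x, blob$y)
  r1 <- poleCenterRatio(part, ints)
  r2 <- poleCenterRatio(part, ints * 137.5)
  expect_equal(r1, r2)
})

test_that("a zero centre sum raises an error for exclusion", {
  m <- rectMask(3L, 9L)
  ints <- ifelse(m$x >= 3 & m$x < 6, 0, 5)
  part <- partitionThirds(m$x, m$y)
  expect_error(poleCenterRatio(part, ints), "centre")
})

test_that("the classifier calls an analytically uniform cell homogeneous", {
  cl <- defaultClassifier()
  res <- classifyCells(cl, data.frame(max_ratio = 1, peak_med = 1,
                                      pole_frac = 1 / 3))
  expect_equal(res$label, "homogeneous")
})

test_that("the logistic fit is invariant to training-row permutation", {
  set.seed(8)
  n <- 200
  feats <- data.frame(
    max_ratio = c(rnorm(n / 2, 1, 0.05), rnorm(n / 2, 3, 0.5)),
    peak_med = c(rnorm(n / 2, 1.1, 0.05), rnorm(n / 2, 2.5, 0.4)),
    pole_frac = c(rnorm(n / 2, 0.34, 0.02), rnorm(n / 2, 0.6, 0.05)))
  labs <- rep(c(FALSE, TRUE), each = n / 2)
  f1 <- fitClassifier(feats, labs)
  perm <- sample(n)
  f2 <- fitClassifier(feats[perm, ], labs[perm])
  expect_equal(f1@coefficients, f2@coefficients, tolerance = 1e-6)
})

test_that("single-class training is rejected", {
  feats <- data.frame(max_ratio = 1:5, peak_med = 1:5, pole_frac = 1:5 / 10)
  expect_error(fitClassifier(feats, rep(TRUE, 5)), "both")
})

test_that("classifier round-trips through its plain-text serialization", {
  cl <- defaultClassifier()
  tmp <- tempfile(fileext = ".txt")
  writeClassifier(cl, tmp)
  cl2 <- readClassifier(tmp)
  expect_equal(cl@coefficients, cl2@coefficients)
  expect_equal(cl@threshold, cl2@threshold)
})

test_that("polarized frequency counts are exact", {
  rec <- data.frame(cell_id = 1:10, frame = 0L,
                    label = c(rep("polarized", 4), rep("homogeneous", 6)))
  fr <- polarizedFrequency(rec, frame_interval = 0.5)
  expect_equal(fr$fraction, 0.4)
  expect_equal(fr$n, 10L)
  rec$label <- "homogeneous"
  expect_equal(polarizedFrequency(rec)$fraction, 0)
  expect_warning(polarizedFrequency(rec[0, ]), "undefined|no classified")
})

test_that("identical channels give diagonal ratio pairs with correlation 1", {
  sim <- cachedSim("polarizedColony", simulationConfig(
    seed = 71, n_frames = 10L, n_initial = 40L, arrest_frame = 0L,
    polarization_onset_mean = 1.5, polarization_onset_sd = 0.75))
  stack2 <- frameStack(list(pvd = sim$stack@data$pvd,
                            pvd2 = sim$stack@data$pvd),
                       frameInterval(sim$stack), pixelSize(sim$stack))
  cells <- measureStack(sim$labels, stack2)
  lastF <- max(cells$frame)
  pairs <- channelRatioPairs(sim$labels, stack2,
                             cells[cells$frame == lastF, , drop = FALSE],
                             channels = c("pvd", "pvd2"))
  expect_equal(pairs$ratio_1, pairs$ratio_2)
  expect_equal(attr(pairs, "correlation"), 1)
})

test_that("co-localized reporter foci correlate across channels", {
  sim <- cachedSim("reporterColony", simulationConfig(
    seed = 83, n_frames = 8L, n_initial = 40L, arrest_frame = 0L,
    reporter = TRUE, polarization_onset_mean = 1, polarization_onset_sd = 0.5))
  cells <- measureStack(sim$labels, sim$stack)
  lastF <- max(cells$frame)
  pairs <- channelRatioPairs(sim$labels, sim$stack,
                             cells[cells$frame == lastF, , drop = FALSE],
                             channels = c("pvd", "reporter"))
  expect_gte(attr(pairs, "correlation"), 0.8)
})

test_that("a uniform channel keeps its ratios near 1 regardless of the other", {
  sim <- cachedSim("reporterColony", simulationConfig(
    seed = 83, n_frames = 8L, n_initial = 40L, arrest_frame = 0L,
    reporter = TRUE, polarization_onset_mean = 1, polarization_onset_sd = 0.5))
  # swap the reporter for the phase body channel: uniform over the cell
  stack2 <- frameStack(list(pvd = sim$stack@data$pvd,
                            flat = sim$stack@data$phase),
                       frameInterval(sim$stack), pixelSize(sim$stack))
  cells <- measureStack(sim$labels, stack2)
  lastF <- max(cells$frame)
  pairs <- channelRatioPairs(sim$labels, stack2,
                             cells[cells$frame == lastF, , drop = FALSE],
                             channels = c("pvd", "flat"),
                             background = "none")
  expect_lt(stats::median(abs(pairs$ratio_2 - 1)), 0.25)
})

test_that("max_ratio over a track bounds every per-frame ratio", {
  sim <- smallColony()
  cells <- measureStack(sim$labels, sim$stack)
  pol <- quantifyPolarization(sim$labels, sim$stack, cells)
  trk <- trackCells(sim$labels, cells, frame_interval = 0.5)
  key <- paste(pol$frame, pol$cell_id)
  for (tid in unique(trk$tracks$track_id)[1:10]) {
    tr <- trk$tracks[trk$tracks$track_id == tid, ]
    rr <- pol$max_ratio[match(paste(tr$frame, tr$cell_id), key)]
    rr <- rr[!is.na(rr)]
    if (length(rr)) expect_true(all(max(rr) >= rr))
  }
})
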