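# Shared fixtures, built in code. Simulations are cached per test run so
# several test files can reuse the same rendered colony.

.fixtureCache <- new.env(parent = emptyenv())

cachedSim <- function(key, config) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, simulateStack(config), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# a small noise-free growing colony used across modules
smallColony <- function() {
  cachedSim("smallColony", simulationConfig(
    seed = 401L, n_frames = 24L, n_initial = 4L, carrying_capacity = 24L,
    shot_noise = FALSE, read_noise_sd = 0))
}

# axis-aligned rectangular mask, 0-based pixel coordinates
rectMask <- function(nrowpx, ncolpx, x0 = 0L, y0 = 0L) {
  list(x = rep(x0 + seq_len(ncolpx) - 1L, each = nrowpx),
       y = rep(y0 + seq_len(nrowpx) - 1L, times = ncolpx))
}

# label matrix + image list from a mask and per-pixel intensities
maskToFrame <- function(mask, intensity, H = 32L, W = 32L) {
  lab <- matrix(0L, H, W)
  img <- matrix(0, H, W)
  idx <- cbind(mask$y + 1L, mask$x + 1L)
  lab[idx] <- 1L
  img[idx] <- intensity
  list(labels = lab, image = img)
}

# independent brute-force oracle: per-pixel thirds classification and sums,
# written as plain loops so it shares nothing with the implementation
bruteThirds <- function(x, y, intensity) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  sxx <- sxx / n; syy <- syy / n; sxy <- sxy / n
  # leading eigenvector of the 2x2 covariance, angle folded into [0, pi)
  ang <- 0.5 * atan2(2 * sxy, sxx - syy)
  cands <- c(ang, ang + pi / 2)
  val <- vapply(cands, function(a)
    cos(a)^2 * sxx + 2 * cos(a) * sin(a) * sxy + sin(a)^2 * syy, numeric(1))
  theta <- cands[which.max(val)] %% pi
  ux <- cos(theta); uy <- sin(theta)
  proj <- numeric(n)
  for (i in seq_len(n)) proj[i] <- (x[i] - mx) * ux + (y[i] - my) * uy
  lo <- min(proj); hi <- max(proj)
  reg <- integer(n)
  bdist <- Inf
  for (i in seq_len(n)) {
    t <- (proj[i] - lo) / (hi - lo)
    reg[i] <- if (t < 1 / 3) 1L else if (t < 2 / 3) 2L else 3L
    bdist <- min(bdist, abs(t - 1 / 3), abs(t - 2 / 3))
  }
  sums <- c(a = sum(intensity[reg == 1L]),
            center = sum(intensity[reg == 2L]),
            b = sum(intensity[reg == 3L]))
  counts <- c(a = sum(reg == 1L), center = sum(reg == 2L),
              b = sum(reg == 3L))
  list(sums = sums, counts = counts, theta = theta, boundary_dist = bdist)
}

# random 4-connected blob grown from a seed pixel; elongated = TRUE biases
# growth along x so the principal axis is unambiguous
randomBlob <- function(npix, H = 24L, W = 36L, elongated = FALSE) {
  prob <- if (elongated) c(0.38, 0.38, 0.12, 0.12) else rep(0.25, 4)
  taken <- matrix(FALSE, H, W)
  cur <- c(sample(8:16, 1), sample(12:20, 1))
  taken[cur[1], cur[2]] <- TRUE
  cells <- list(cur)
  while (length(cells) < npix) {
    base <- cells[[sample(length(cells), 1)]]
    step <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))[
      sample(4, 1, prob = prob), ]
    nxt <- base + step
    if (nxt[1] < 1 || nxt[1] > H || nxt[2] < 1 || nxt[2] > W) next
    if (!taken[nxt[1], nxt[2]]) {
      taken[nxt[1], nxt[2]] <- TRUE
      cells[[length(cells) + 1]] <- nxt
    }
  }
  m <- do.call(rbind, cells)
  list(x = m[, 2] - 1L, y = m[, 1] - 1L)
}

# elongated blob with an unambiguous principal axis (aspect >= 1.6) and no
# pixel within floating-point reach of a thirds boundary (the half-open
# region convention is only defined up to exact arithmetic there)
elongatedBlob <- function(npix) {
  repeat {
    blob <- randomBlob(npix, elongated = TRUE)
    cx <- blob$x - mean(blob$x); cy <- blob$y - mean(blob$y)
    ev <- eigen(cov(cbind(cx, cy)), symmetric = TRUE)$values
    if (sqrt(ev[1] / max(ev[2], 1e-9)) < 1.6) next
    bt <- bruteThirds(blob$x, blob$y, rep(1, length(blob$x)))
    if (bt$boundary_dist > 1e-6) return(blob)
  }
}

# Independent direct-rasterization oracle for a single homogeneous cell:
# same optical model as the renderer (projected thin-shell chord, cap density
# correction, axial flattening against the PSF, normalized Gaussian PSF), but
# implemented with scalar loops and shift-and-add circular convolution,
# sharing no code with the package.
directRasterOracle <- function(cx, cy, theta, len_um, cfg, total, dims) {
  H <- dims[1]; W <- dims[2]
  ps <- cfg@pixel_size
  R <- (cfg@cell_width / 2) / ps
  thick <- max(1, 0.1 / ps) * 0.8
  half <- max(len_um / (2 * ps) - R, 0.05)
  ux <- cos(theta); uy <- sin(theta)
  e0x <- cx - ux * half; e0y <- cy - uy * half
  e1x <- cx + ux * half; e1y <- cy + uy * half
  sigPsf <- max(cfg@psf_sigma / ps, 1e-3)
  r <- max(1L, ceiling(3 * sigPsf))
  kern <- matrix(0, 2 * r + 1, 2 * r + 1)
  for (i in -r:r) for (j in -r:r)
    kern[i + r + 1, j + r + 1] <- exp(-(i^2 + j^2) / (2 * sigPsf^2))
  kern <- kern / sum(kern)

  pad <- R + 1.5 + r
  x0 <- max(floor(min(e0x, e1x) - pad), 0)
  x1 <- min(ceiling(max(e0x, e1x) + pad), W - 1)
  y0 <- max(floor(min(e0y, e1y) - pad), 0)
  y1 <- min(ceiling(max(e0y, e1y) + pad), H - 1)

  circConv <- function(m, k) {
    out <- matrix(0, nrow(m), ncol(m))
    rr <- (nrow(k) - 1) / 2
    for (i in -rr:rr) for (j in -rr:rr) {
      w <- k[i + rr + 1, j + rr + 1]
      if (w == 0) next
      ri <- ((seq_len(nrow(m)) - 1 + i) %% nrow(m)) + 1
      ci <- ((seq_len(ncol(m)) - 1 + j) %% ncol(m)) + 1
      out[ri, ci] <- out[ri, ci] + w * m
    }
    out
  }

  # per-pixel geometry over the box, scalar loops
  xs <- x0:x1; ys <- y0:y1
  nx <- length(xs); ny <- length(ys)
  wmat <- matrix(0, ny, nx)
  projm <- matrix(NA_real_, ny, nx)
  L2 <- (e1x - e0x)^2 + (e1y - e0y)^2
  Ro <- R; Ri <- max(R - thick, 0.25 * R)
  for (a in seq_len(ny)) for (b in seq_len(nx)) {
    px <- xs[b]; py <- ys[a]
    t <- ((px - e0x) * (e1x - e0x) + (py - e0y) * (e1y - e0y)) / L2
    tc <- min(max(t, 0), 1)
    qx <- e0x + tc * (e1x - e0x); qy <- e0y + tc * (e1y - e0y)
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    if (d > R) next
    s <- (t - 0.5) * sqrt(L2)
    w <- sqrt(max(Ro^2 - d^2, 0)) - sqrt(max(Ri^2 - d^2, 0))
    z <- abs(s) - half
    if (z > Ri && w > 0) {
      zc <- min(z, Ro - 0.5)
      w <- w * (Ro^2 - Ri^2) / max(Ro^2 - zc^2, 1e-6)
    }
    wmat[a, b] <- w
    projm[a, b] <- (px - cx) * ux + (py - cy) * uy
  }

  # axial flattening (two rounds) against the blurred in-mask profile,
  # along the rasterized mask's own principal axis, with the bin count a
  # multiple of three
  inm <- !is.na(projm)
  mxs <- c(); mys <- c()
  for (a in seq_len(ny)) for (b in seq_len(nx))
    if (inm[a, b]) { mxs <- c(mxs, xs[b]); mys <- c(mys, ys[a]) }
  pca <- bruteThirds(mxs, mys, rep(1, length(mxs)))
  pux <- cos(pca$theta); puy <- sin(pca$theta)
  mcx <- mean(mxs); mcy <- mean(mys)
  for (a in seq_len(ny)) for (b in seq_len(nx))
    if (inm[a, b])
      projm[a, b] <- (xs[b] - mcx) * pux + (ys[a] - mcy) * puy
  rng <- range(projm[inm])
  nb <- 3L * max(2L, as.integer(round(diff(rng) / 9)))
  tt <- (projm - rng[1]) / diff(rng)
  binm <- pmin(floor(tt * nb) + 1L, nb)
  for (it in 1:2) {
    bl <- circConv(wmat, kern)
    bsum <- rep(0, nb)
    for (a in seq_len(ny)) for (b in seq_len(nx))
      if (inm[a, b]) bsum[binm[a, b]] <- bsum[binm[a, b]] + bl[a, b]
    nonzero <- bsum > 0
    gain <- rep(1, nb)
    gain[nonzero] <- pmin(pmax(mean(bsum[nonzero]) / bsum[nonzero], 0.5), 3)
    for (a in seq_len(ny)) for (b in seq_len(nx))
      if (inm[a, b]) wmat[a, b] <- wmat[a, b] * gain[binm[a, b]]
  }

  img <- matrix(0, H, W)
  img[cbind(rep(ys, times = nx) + 1L, rep(xs, each = ny) + 1L)] <-
    as.vector(wmat) / sum(wmat) * total
  circConv(img, kern)
}
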