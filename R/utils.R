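# Internal geometry and RNG helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-cell sub-seed: draws for cell `id` do not depend on the
# order in which cells are processed. Kept below 2^31.
cellSeed <- function(seed, id, salt = 0L) {
  as.integer((as.double(seed %% 1000003L) * 69621 + as.double(id) * 7919 +
                as.double(salt) * 104729) %% 2147483629) + 1L
}

# All per-cell random quantities, drawn in one fixed order from the cell's
# own sub-stream.
cellDraws <- function(seed, id) {
  withSeed(cellSeed(seed, id), {
    list(
      lag      = rnorm(1),   # z-score for lag duration
      onset    = rnorm(1),   # z-score for polarization onset delay
      depol    = rnorm(1),   # z-score for depolarization delay
      div_frac = runif(1, 0.45, 0.55),  # division asymmetry
      pole_u   = runif(1),   # new- vs old-pole focus choice
      jitter   = rnorm(1, 0, 0.05),     # orientation jitter at birth
      place    = runif(4),   # founder placement (angle, radius, theta, length)
      init_pol = runif(1),   # initially-polarized draw
      np_u     = runif(1)    # founder new-pole end choice
    )
  })
}

# Distance from points (px, py) to segment (ax, ay)-(bx, by); vectorized over
# points. Also returns the signed axial coordinate of each point's projection
# onto the (unclamped) segment axis, measured from the segment midpoint.
distToSegment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx * vx + vy * vy
  if (L2 < 1e-12) {
    d <- sqrt((px - ax)^2 + (py - ay)^2)
    return(list(d = d, s = rep(0, length(px))))
  }
  t <- ((px - ax) * vx + (py - ay) * vy) / L2
  tc <- pmin(pmax(t, 0), 1)
  qx <- ax + tc * vx; qy <- ay + tc * vy
  list(d = sqrt((px - qx)^2 + (py - qy)^2),
       s = (t - 0.5) * sqrt(L2))
}

# Principal axis of a pixel cloud: returns centre, unit vector u with angle in
# [0, pi), and the eigenvalue ratio (major/minor). Optional pixel weights.
principalAxis <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  dx <- x - mx; dy <- y - my
  cxx <- sum(w * dx * dx); cyy <- sum(w * dy * dy); cxy <- sum(w * dx * dy)
  cm <- matrix(c(cxx, cxy, cxy, cyy), 2)
  eg <- eigen(cm, symmetric = TRUE)
  u <- eg$vectors[, 1]
  theta <- atan2(u[2], u[1]) %% pi
  u <- c(cos(theta), sin(theta))
  lam <- pmax(eg$values, 0)
  list(cx = mx, cy = my, ux = u[1], uy = u[2], theta = theta,
       aspect = sqrt((lam[1] + 1e-12) / (lam[2] + 1e-12)))
}

# Centred moving average with partial windows at the edges; window 1 is the
# identity.
movingAverage <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# Normalized 2D Gaussian kernel (odd size, radius >= 3 sigma).
gaussianKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  ax <- seq(-r, r)
  k <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-ax^2 / (2 * sigma^2)))
  k / sum(k)
}

# Area of the convex hull of a set of pixel centres, treating each pixel as a
# unit square (corners included), via the shoelace formula.
convexHullArea <- function(x, y) {
  xs <- c(x - 0.5, x - 0.5, x + 0.5, x + 0.5)
  ys <- c(y - 0.5, y + 0.5, y - 0.5, y + 0.5)
  h <- grDevices::chull(xs, ys)
  hx <- xs[h]; hy <- ys[h]
  n <- length(h)
  if (n < 3) return(length(x))
  j <- c(2:n, 1)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}
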