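# Rasterization of ground-truth cell states into noisy fluorescence frames.

# Per-pixel fluorophore weights for one cell on a local grid.
#
# The periplasmic signal is the 2D projection of a thin 3D spherocylindrical
# shell: at distance d from the medial axis the projected column is the chord
# through an annulus (outer radius R, inner radius R - t). By the hat-box
# property a thin shell carries uniform fluorophore per unit axial length, so
# a homogeneous cell projects a flat long-axis profile; the finite-thickness
# deficit in the cap slices is corrected analytically.
.shellWeights <- function(d, s, half, R, thick) {
  Ro <- R
  Ri <- max(R - thick, 0.25 * R)
  w <- sqrt(pmax(Ro^2 - d^2, 0)) - sqrt(pmax(Ri^2 - d^2, 0))
  z <- abs(s) - half            # axial depth into the cap region
  zc <- pmin(z, Ro - 0.5)       # cap the correction at half a pixel from tip
  inCap <- z > Ri & w > 0
  if (any(inCap)) {
    g <- (Ro^2 - Ri^2) / pmax(Ro^2 - zc[inCap]^2, 1e-6)
    w[inCap] <- w[inCap] * g
  }
  w
}

# Axial flattening: the PSF bleeds disproportionately much signal out of the
# mask at the cell tips, so the *measured* long-axis profile of a raw shell
# dips at the poles. Blur the candidate weights with the rendering PSF on a
# local grid, measure the in-mask axial mass profile along the principal
# axis of the rasterized mask (the same axis the measurement stage will
# use), and rescale the weights per ~3 px axial bin so that the rendered
# homogeneous cell reads flat. The bin count is a multiple of 3, so equal
# mass per bin implies equal mass per axial third.
.flattenAxial <- function(w, gx, gy, lx, ly, nx, ny, psfK, iters = 2L) {
  pa <- principalAxis(gx, gy)
  proj <- (gx - pa$cx) * pa$ux + (gy - pa$cy) * pa$uy
  rng <- range(proj)
  if (diff(rng) < 1e-9) return(w)
  tt <- (proj - rng[1]) / diff(rng)
  nb <- 3L * max(2L, as.integer(round(diff(rng) / 9)))
  bin <- pmin(floor(tt * nb) + 1L, nb)
  idx <- cbind(ly, lx)
  for (it in seq_len(iters)) {
    wbox <- matrix(0, ny, nx)
    wbox[idx] <- w
    bl <- EBImage::filter2(wbox, psfK, boundary = "circular")
    bsum <- tapply(bl[idx], bin, sum)
    gain <- rep(1, nb)
    gain[as.integer(names(bsum))] <-
      pmin(pmax(mean(bsum) / pmax(bsum, 1e-12), 0.5), 3)
    w <- w * gain[bin]
  }
  w
}

#' Render ground truth into a multi-channel image stack and label images
#'
#' Draws every cell as a 2D spherocylinder. The fluorophore of a homogeneous
#' cell is painted as the projection of a thin periplasmic shell (uniform per
#' unit length along the long axis); a polarized cell relocates
#' `focus_fraction` of its fluorophore into an isotropic Gaussian spot inside
#' the focus pole cap. A phase-contrast-like channel renders the full cell
#' body. Each frame is convolved with a normalized Gaussian PSF (circular
#' boundary, so total intensity is conserved), then optionally Poisson
#' resampled and degraded with additive Gaussian read noise. A ground-truth
#' label image assigns each pixel to the nearest cell (smallest normalized
#' axis distance).
#'
#' @param truth a [SimTruth-class].
#' @param config a [SimulationConfig-class]; defaults to the truth's own.
#' @return a list with elements `stack` (a [FrameStack-class] with channels
#'   `"phase"`, `"pvd"` and, if configured, `"reporter"`) and `labels`
#'   (an integer `height x width x n_frames` array of cell ids).
#' @examples
#' truth <- simulateColony(simulationConfig(seed = 3, n_frames = 4L,
#'                                          n_initial = 2L))
#' ren <- renderFrames(truth)
#' ren$stack
#' @export
renderFrames <- function(truth, config = simConfig(truth)) {
  stopifnot(is(truth, "SimTruth"), is(config, "SimulationConfig"))
  cfg <- config
  H <- truth@dims[1]; W <- truth@dims[2]
  nF <- cfg@n_frames
  ps <- cfg@pixel_size
  R <- (cfg@cell_width / 2) / ps
  thick <- max(1, 0.1 / ps) * 0.8        # shell thickness, px
  sigFocus <- cfg@focus_sigma / ps
  chans <- c("phase", "pvd", if (cfg@reporter) "reporter")
  out <- lapply(chans, function(ch) array(0, dim = c(H, W, nF)))
  names(out) <- chans
  labels <- array(0L, dim = c(H, W, nF))
  psfK <- gaussianKernel(max(cfg@psf_sigma / ps, 1e-3))
  cells <- truth@cells
  clipped <- integer(0)

  for (f in 0L:(nF - 1L)) {
    fc <- cells[cells$frame == f, , drop = FALSE]
    img <- list()
    for (ch in chans) img[[ch]] <- matrix(0, H, W)
    lab <- matrix(0L, H, W)
    score <- matrix(Inf, H, W)

    for (k in seq_len(nrow(fc))) {
      cc <- fc[k, ]
      half <- max(cc$length_um / (2 * ps) - R, 0.05)
      u <- c(cos(cc$theta), sin(cc$theta))
      e0 <- c(cc$cx, cc$cy) - u * half
      e1 <- c(cc$cx, cc$cy) + u * half
      pad <- R + 1.5 + (nrow(psfK) - 1) / 2
      x0 <- floor(min(e0[1], e1[1]) - pad); x1 <- ceiling(max(e0[1], e1[1]) + pad)
      y0 <- floor(min(e0[2], e1[2]) - pad); y1 <- ceiling(max(e0[2], e1[2]) + pad)
      if (x0 < 0 || y0 < 0 || x1 > W - 1 || y1 > H - 1)
        clipped <- c(clipped, cc$id)
      x0 <- max(x0, 0); y0 <- max(y0, 0)
      x1 <- min(x1, W - 1); y1 <- min(y1, H - 1)
      if (x1 < x0 || y1 < y0) next
      xs <- x0:x1; ys <- y0:y1
      gx <- rep(xs, each = length(ys))
      gy <- rep(ys, times = length(xs))
      dpr <- distToSegment(gx, gy, e0[1], e0[2], e1[1], e1[2])
      inMask <- dpr$d <= R
      if (!any(inMask)) next
      ri <- gy[inMask] + 1L; ci <- gx[inMask] + 1L
      idxm <- cbind(ri, ci)

      # label by smallest normalized axis distance
      sc <- dpr$d[inMask] / R
      better <- sc < score[idxm]
      if (any(better)) {
        score[idxm[better, , drop = FALSE]] <- sc[better]
        lab[idxm[better, , drop = FALSE]] <- cc$id
      }

      # phase-contrast-like body (projected solid spherocylinder)
      body <- sqrt(pmax(R^2 - dpr$d[inMask]^2, 0))
      if (sum(body) > 0) {
        bodyAmt <- cfg@phase_intensity * cc$length_um
        img$phase[idxm] <- img$phase[idxm] + bodyAmt * body / sum(body)
      }

      # fluorophore channels
      tot <- cc$total_fluorophore
      if (tot > 0) {
        w <- .shellWeights(dpr$d[inMask], dpr$s[inMask], half, R, thick)
        xm <- gx[inMask]; ym <- gy[inMask]
        w <- .flattenAxial(w, xm, ym, xm - x0 + 1L, ym - y0 + 1L,
                           x1 - x0 + 1L, y1 - y0 + 1L, psfK)
        sw <- sum(w)
        fFoc <- if (cc$polarized) cfg@focus_fraction else 0
        for (ch in setdiff(chans, "phase")) {
          amt <- if (ch == "pvd") tot
                 else cfg@reporter_intensity * cc$length_um
          if (sw > 0)
            img[[ch]][idxm] <- img[[ch]][idxm] + amt * (1 - fFoc) * w / sw
          if (fFoc > 0) {
            npDir <- c(cc$new_pole_x, cc$new_pole_y)
            if (cc$focus_pole == "old") npDir <- -npDir
            ctr <- c(cc$cx, cc$cy) + npDir * (half + 0.2 * R)
            g <- exp(-((gx[inMask] - ctr[1])^2 + (gy[inMask] - ctr[2])^2) /
                       (2 * sigFocus^2))
            sg <- sum(g)
            if (sg > 0)
              img[[ch]][idxm] <- img[[ch]][idxm] + amt * fFoc * g / sg
          }
        }
      }
    }

    for (ch in chans) {
      m <- EBImage::filter2(img[[ch]], psfK, boundary = "circular")
      m[m < 0] <- 0
      if (cfg@shot_noise)
        m <- matrix(stats::rpois(length(m), m), H, W)
      if (cfg@read_noise_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, cfg@read_noise_sd), H, W)
      m[m < 0] <- 0
      out[[ch]][, , f + 1L] <- m
    }
    labels[, , f + 1L] <- lab
  }

  if (length(clipped))
    warning("cells clipped at the field edge: ",
            paste(sort(unique(clipped)), collapse = ", "))
  stack <- frameStack(out, cfg@frame_interval, ps)
  list(stack = stack, labels = labels)
}

#' Simulate and render in one deterministic call
#'
#' Runs [simulateColony()] and [renderFrames()] with all randomness (both the
#' colony's stochastic events and the rendering noise) derived from the
#' configuration seed, so identical configurations give bit-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `truth`, `stack`, `labels`.
#' @export
simulateStack <- function(config) {
  truth <- simulateColony(config)
  ren <- withSeed(cellSeed(config@seed, 0L, salt = 17L),
                  renderFrames(truth, config))
  list(truth = truth, stack = ren$stack, labels = ren$labels)
}
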