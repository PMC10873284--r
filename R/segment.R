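#' Segment one frame into labelled cell masks
#'
#' Background/foreground separation by Gaussian smoothing and Otsu
#' thresholding, followed by a distance-transform watershed to separate
#' touching cells. A stand-in for full segmentation suites, adequate for the
#' synthetic images this package generates and for well-resolved real frames.
#'
#' @param image 2D numeric intensity matrix (rows = y).
#' @param sigma smoothing sigma before thresholding, pixels.
#' @param min_area minimum object area retained, pixels.
#' @param tolerance,ext watershed parameters (see [EBImage::watershed()]).
#' @param refine_frac per-object boundary refinement: pixels below this
#'   fraction of the object's (98th-percentile) peak are dropped; 0 disables.
#' @return an integer label matrix: background 0, cells 1..n.
#' @examples
#' img <- matrix(0, 40, 40); img[10:20, 5:30] <- 100
#' table(segmentFrame(img))
#' @export
segmentFrame <- function(image, sigma = 1, min_area = 20L,
                         tolerance = 1, ext = 1, refine_frac = 0.6) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image contains non-finite values")
  rng <- range(image)
  if (diff(rng) <= 0) {
    warning("empty foreground: image is constant")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  x <- (image - rng[1]) / diff(rng)
  xs <- EBImage::gblur(x, sigma = sigma)
  th <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  bw <- xs > th
  if (!any(bw)) {
    warning("empty foreground after thresholding")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  bw <- EBImage::fillHull(bw)
  # refine each object at a fraction of its own peak: the global threshold
  # keeps the PSF halo, whose intensity at the true boundary sits near half
  # the local maximum
  if (refine_frac > 0) {
    lab0 <- EBImage::bwlabel(bw)
    for (id in seq_len(max(lab0))) {
      idx <- which(lab0 == id)
      if (length(idx) < 4L) next
      thr <- refine_frac * stats::quantile(xs[idx], 0.98)
      bw[idx[xs[idx] < thr]] <- FALSE
    }
    bw <- EBImage::fillHull(bw)
    if (!any(bw)) {
      warning("empty foreground after refinement")
      return(matrix(0L, nrow(image), ncol(image)))
    }
  }
  dm <- EBImage::distmap(bw)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                               ext = ext))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area)
  out <- match(lab, keep)
  out[is.na(out)] <- 0L
  matrix(as.integer(out), nrow(image), ncol(image))
}

#' Segment every frame of a stack
#'
#' Applies [segmentFrame()] to the chosen channel of each frame. Defaults to
#' the fluorescence channel (cells are bright against a dark pad) and falls
#' back to the phase-contrast-like channel when the fluorescence channel is
#' effectively empty, as for non-producer strains.
#'
#' @param stack a [FrameStack-class].
#' @param channel channel to segment, or `"auto"`.
#' @param ... passed to [segmentFrame()].
#' @return integer array `height x width x n_frames` of labels.
#' @export
segmentStack <- function(stack, channel = "auto", ...) {
  stopifnot(is(stack, "FrameStack"))
  if (channel == "auto") {
    fluo <- setdiff(channelNames(stack), "phase")
    channel <- if (length(fluo)) fluo[1] else channelNames(stack)[1]
    sig <- stats::quantile(stack@data[[channel]], 0.999)
    if (sig <= 5 * stats::median(stack@data[[channel]]) + 1e-9 &&
        "phase" %in% channelNames(stack))
      channel <- "phase"
  }
  d <- stack@data[[channel]]
  out <- array(0L, dim = dim(d))
  for (f in seq_len(dim(d)[3])) out[, , f] <- segmentFrame(d[, , f], ...)
  out
}

# qc codes, in priority order
.qcFlag <- function(area, touchesEdge, solidity, min_area, solidity_min) {
  if (area < min_area) return("tiny")
  if (touchesEdge) return("boundary")
  if (solidity < solidity_min) return("shape_anomaly")
  "ok"
}

#' Measure one labelled frame into per-cell observations
#'
#' Computes, for every label, the geometry (area, centroid, principal-axis
#' orientation in `[0, pi)`, axis length and width from the pixel-projection
#' extents) and per-channel intensity sums and means. Near-isotropic masks
#' (aspect ratio below `aspect_iso`) take their orientation from the
#' intensity-weighted pixel covariance of the first fluorescence channel.
#' Quality flags: `tiny` (area below `min_area`), `boundary` (mask touches
#' the frame edge), `shape_anomaly` (solidity below `solidity_min`), else
#' `ok`; only `ok` cells enter downstream statistics.
#'
#' Coordinates are 0-based (pixel centres at integers, row-major y/x).
#'
#' @param labels integer label matrix.
#' @param images named list of intensity matrices (one per channel).
#' @param frame 0-based frame index recorded in the output.
#' @param pixel_size micrometres per pixel.
#' @param min_area,solidity_min,aspect_iso QC thresholds.
#' @return data.frame, one row per cell: `frame`, `cell_id`, `area`, `cx`,
#'   `cy`, `orientation`, `axis_length_um`, `width_um`, `solidity`,
#'   `qc_flag`, and `<channel>_sum` / `<channel>_mean` per channel.
#' @export
measureFrame <- function(labels, images, frame = 0L, pixel_size = 0.1,
                         min_area = 20L, solidity_min = 0.8,
                         aspect_iso = 1.2) {
  stopifnot(is.matrix(labels))
  if (!is.list(images)) images <- list(intensity = images)
  for (im in images)
    if (!all(dim(im) == dim(labels)))
      stop("label/image shape mismatch")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L)
    return(.emptyCells(names(images)))
  H <- nrow(labels); W <- ncol(labels)
  pix <- split(seq_along(labels)[labels > 0L], labels[labels > 0L])
  fluoCh <- setdiff(names(images), "phase")
  wCh <- if (length(fluoCh)) fluoCh[1] else names(images)[1]
  rows <- lapply(ids, function(id) {
    idx <- pix[[as.character(id)]]
    ri <- (idx - 1L) %% H + 1L
    ci <- (idx - 1L) %/% H + 1L
    x <- ci - 1; y <- ri - 1
    area <- length(idx)
    pa <- principalAxis(x, y)
    if (pa$aspect < aspect_iso) {
      wInt <- images[[wCh]][idx]
      if (sum(wInt) > 0) pa <- principalAxis(x, y, w = wInt)
    }
    proj <- (x - pa$cx) * pa$ux + (y - pa$cy) * pa$uy
    perp <- -(x - pa$cx) * pa$uy + (y - pa$cy) * pa$ux
    axisLen <- (diff(range(proj)) + 1) * pixel_size
    width <- (diff(range(perp)) + 1) * pixel_size
    sol <- area / max(convexHullArea(x, y), 1)
    touches <- any(ri == 1L | ri == H | ci == 1L | ci == W)
    qc <- .qcFlag(area, touches, sol, min_area, solidity_min)
    res <- data.frame(frame = frame, cell_id = id, area = area,
                      cx = pa$cx, cy = pa$cy, orientation = pa$theta,
                      axis_length_um = max(axisLen, width),
                      width_um = min(axisLen, width),
                      solidity = sol, qc_flag = qc,
                      stringsAsFactors = FALSE)
    for (ch in names(images)) {
      v <- images[[ch]][idx]
      res[[paste0(ch, "_sum")]] <- sum(v)
      res[[paste0(ch, "_mean")]] <- mean(v)
    }
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyCells <- function(channels) {
  out <- data.frame(frame = integer(0), cell_id = integer(0),
                    area = integer(0), cx = numeric(0), cy = numeric(0),
                    orientation = numeric(0), axis_length_um = numeric(0),
                    width_um = numeric(0), solidity = numeric(0),
                    qc_flag = character(0), stringsAsFactors = FALSE)
  for (ch in channels) {
    out[[paste0(ch, "_sum")]] <- numeric(0)
    out[[paste0(ch, "_mean")]] <- numeric(0)
  }
  out
}

#' Measure every frame of a label stack
#'
#' @param labels integer array `height x width x n_frames` (from
#'   [segmentStack()], [renderFrames()], or [readLabelStack()]).
#' @param stack the matching [FrameStack-class].
#' @param ... passed to [measureFrame()].
#' @return row-bound data.frame of per-cell observations (see
#'   [measureFrame()]); frames are 0-based.
#' @export
measureStack <- function(labels, stack, ...) {
  stopifnot(is(stack, "FrameStack"), length(dim(labels)) == 3L)
  nF <- dim(labels)[3]
  if (nF != nFrames(stack)) stop("label/stack frame count mismatch")
  rows <- lapply(seq_len(nF), function(f) {
    imgs <- lapply(stack@data, function(d) d[, , f])
    measureFrame(labels[, , f], imgs, frame = f - 1L,
                 pixel_size = pixelSize(stack), ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pixel coordinates (0-based x, y) of one cell in one frame of a label stack.
cellPixels <- function(labels, frame, id) {
  lab <- if (length(dim(labels)) == 3L) labels[, , frame + 1L] else labels
  idx <- which(lab == id)
  if (length(idx) == 0L)
    stop("no pixels for cell ", id, " in frame ", frame)
  H <- nrow(lab)
  list(x = (idx - 1L) %/% H, y = (idx - 1L) %% H, idx = idx)
}
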