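#' Long-axis fluorescence profile of one cell
#'
#' Projects every mask pixel onto the cell's principal axis, min-max
#' normalizes the projections to `[0, 1]`, and averages pixel intensities in
#' `n_bins` equal-width bins (half-open, last bin closed). Empty bins are
#' filled by linear interpolation and flagged.
#'
#' When the new pole is known, orient the profile with `flip` so that
#' position 0 is the old pole and polar peaks appear near 1.
#'
#' @param x,y 0-based pixel coordinates of the mask.
#' @param intensity pixel intensities (same length).
#' @param n_bins number of bins (>= 3).
#' @param cell_id,frame identifiers carried into the output.
#' @param orientation optional axis angle (radians); default: principal axis
#'   of the mask.
#' @param flip reverse the axis direction (old pole at 0 convention).
#' @return data.frame: `cell_id`, `frame`, `bin`, `position` (bin centre in
#'   `[0,1]`), `intensity`, `interpolated`.
#' @export
axisProfile <- function(x, y, intensity, n_bins = 20L, cell_id = NA_integer_,
                        frame = NA_integer_, orientation = NULL,
                        flip = FALSE) {
  stopifnot(length(x) == length(y), length(x) == length(intensity))
  if (n_bins < 3L) stop("n_bins must be >= 3")
  if (is.null(orientation)) {
    pa <- principalAxis(x, y)
    u <- c(pa$ux, pa$uy); ctr <- c(pa$cx, pa$cy)
  } else {
    u <- c(cos(orientation), sin(orientation))
    ctr <- c(mean(x), mean(y))
  }
  proj <- (x - ctr[1]) * u[1] + (y - ctr[2]) * u[2]
  rng <- range(proj)
  if (diff(rng) < 1e-9)
    stop("degenerate axis for cell ", cell_id, " (zero projection variance)")
  t <- (proj - rng[1]) / diff(rng)
  if (flip) t <- 1 - t
  bin <- pmin(floor(t * n_bins) + 1L, n_bins)
  vals <- rep(NA_real_, n_bins)
  agg <- tapply(intensity, bin, mean)
  vals[as.integer(names(agg))] <- agg
  empty <- is.na(vals)
  if (any(empty)) {
    filled <- which(!empty)
    vals[empty] <- stats::approx(filled, vals[filled], xout = which(empty),
                                 rule = 2)$y
  }
  data.frame(cell_id = cell_id, frame = frame, bin = seq_len(n_bins),
             position = (seq_len(n_bins) - 0.5) / n_bins,
             intensity = vals, interpolated = empty)
}

#' Long-axis profiles for every qc-ok cell in a stack
#'
#' @param labels label array (`height x width x n_frames`).
#' @param stack a [FrameStack-class].
#' @param cells observation table from [measureStack()]; only `qc_flag ==
#'   "ok"` cells are profiled.
#' @param channel intensity channel.
#' @param n_bins bins per profile.
#' @param background `"median"` to subtract the per-frame median background
#'   before profiling, `"none"` to use raw intensities.
#' @return long-format data.frame of [axisProfile()] rows.
#' @export
profileStack <- function(labels, stack, cells, channel = "pvd",
                         n_bins = 20L, background = c("median", "none")) {
  background <- match.arg(background)
  ok <- cells[cells$qc_flag == "ok", , drop = FALSE]
  rows <- vector("list", nrow(ok))
  for (f in sort(unique(ok$frame))) {
    img <- stackFrame(stack, channel, f + 1L)
    if (background == "median") {
      img <- img - stats::median(img)
      img[img < 0] <- 0
    }
    sub <- ok[ok$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      px <- cellPixels(labels, f, sub$cell_id[i])
      rows[[length(rows) + 1L]] <- axisProfile(
        px$x, px$y, img[px$idx], n_bins = n_bins,
        cell_id = sub$cell_id[i], frame = f,
        orientation = sub$orientation[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled, smoothed mean profile across cells
#'
#' Per-bin arithmetic mean over all profiles, then a centred moving-average
#' smoothing. With `smoothing_window = 1` the smoothed profile equals the
#' plain mean exactly.
#'
#' @param profiles long-format profile table from [axisProfile()] /
#'   [profileStack()]; all profiles must share `n_bins`.
#' @param smoothing_window odd moving-average window in bins.
#' @return data.frame: `bin`, `position`, `mean_intensity`,
#'   `smoothed_intensity`, `n` (profiles contributing per bin).
#' @export
pooledProfile <- function(profiles, smoothing_window = 3L) {
  if (nrow(profiles) == 0L) stop("no profiles supplied")
  nb <- unique(tapply(profiles$bin, paste(profiles$cell_id, profiles$frame),
                      max))
  if (length(nb) != 1L)
    stop("profiles have mixed n_bins; pool only compatible profiles")
  nb <- as.integer(nb)
  mu <- tapply(profiles$intensity, profiles$bin, mean)
  n <- tapply(profiles$intensity, profiles$bin, length)
  vals <- as.numeric(mu[as.character(seq_len(nb))])
  data.frame(bin = seq_len(nb), position = (seq_len(nb) - 0.5) / nb,
             mean_intensity = vals,
             smoothed_intensity = movingAverage(vals, smoothing_window),
             n = as.integer(n[as.character(seq_len(nb))]))
}
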