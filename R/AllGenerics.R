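#' @rdname FrameStack-class
#' @param object,x a \code{FrameStack}, \code{SimTruth} or
#'   \code{SimulationConfig} as documented per method.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname FrameStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname SimTruth-class
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))

#' @rdname SimTruth-class
#' @export
setGeneric("truthLineage", function(x) standardGeneric("truthLineage"))

#' @rdname SimTruth-class
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @describeIn FrameStack-class channel names.
#' @export
setMethod("channelNames", "FrameStack", function(x) x@channels)

#' @describeIn FrameStack-class hours between frames.
#' @export
setMethod("frameInterval", "FrameStack", function(x) x@frame_interval)

#' @describeIn FrameStack-class micrometres per pixel.
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixel_size)

#' @describeIn FrameStack-class number of frames.
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@data[[1]])[3])

#' @describeIn SimTruth-class number of simulated frames.
#' @export
setMethod("nFrames", "SimTruth", function(x) x@config@n_frames)

#' @describeIn SimTruth-class the per-cell, per-frame ground-truth table.
#' @export
setMethod("truthCells", "SimTruth", function(x) x@cells)

#' @describeIn SimTruth-class the ground-truth lineage table.
#' @export
setMethod("truthLineage", "SimTruth", function(x) x@lineage)

#' @describeIn SimTruth-class the generating configuration.
#' @export
setMethod("simConfig", "SimTruth", function(x) x@config)

#' Extract one frame of one channel
#'
#' @param x a [FrameStack-class].
#' @param channel channel name.
#' @param frame 1-based frame index.
#' @return a numeric matrix (rows = y, columns = x).
#' @export
stackFrame <- function(x, channel, frame) {
  stopifnot(is(x, "FrameStack"))
  if (!channel %in% x@channels)
    stop("unknown channel '", channel, "'; available: ",
         paste(x@channels, collapse = ", "))
  nf <- dim(x@data[[channel]])[3]
  if (frame < 1L || frame > nf)
    stop("frame index out of range (1..", nf, ")")
  x@data[[channel]][, , frame]
}

#' Construct a FrameStack
#'
#' @param data named list of 3D arrays (y, x, frame), one per channel, or a
#'   named list of lists of matrices.
#' @param frame_interval hours between frames.
#' @param pixel_size micrometres per pixel.
#' @return a [FrameStack-class].
#' @export
frameStack <- function(data, frame_interval, pixel_size) {
  data <- lapply(data, function(d) {
    if (is.list(d)) d <- simplify2array(d)
    if (length(dim(d)) == 2L) d <- array(d, dim = c(dim(d), 1L))
    d
  })
  new("FrameStack", data = data, channels = names(data),
      frame_interval = as.numeric(frame_interval),
      pixel_size = as.numeric(pixel_size))
}

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data[[1]])
  cat("FrameStack:", d[1], "x", d[2], "px,", d[3], "frames\n")
  cat("  channels:      ", paste(object@channels, collapse = ", "), "\n")
  cat("  frame interval:", object@frame_interval, "h\n")
  cat("  pixel size:    ", object@pixel_size, "um/px\n")
})

setMethod("show", "SimTruth", function(object) {
  cc <- object@cells
  cat("SimTruth:", length(unique(cc$id)), "cells over",
      object@config@n_frames, "frames\n")
  last <- cc[cc$frame == max(cc$frame), ]
  cat("  final frame:", nrow(last), "cells,",
      sum(last$polarized), "polarized\n")
  cat("  phases seen: ", paste(unique(cc$phase), collapse = ", "), "\n")
  cat("  canvas:      ", object@dims[1], "x", object@dims[2], "px\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed", object@seed, ")\n")
  cat(sprintf("  %d frames x %.2g h; %.3g um/px\n",
              object@n_frames, object@frame_interval, object@pixel_size))
  cat(sprintf("  cells: width %.2g um, birth %.2g -> division %.2g um, rate %.2g /h\n",
              object@cell_width, object@birth_length, object@division_length,
              object@elongation_rate))
  cat(sprintf("  colony: %d founders, capacity %d, arrest frame %s, release frame %s\n",
              object@n_initial, object@carrying_capacity,
              ifelse(is.na(object@arrest_frame), "none", object@arrest_frame),
              ifelse(is.na(object@release_frame), "none", object@release_frame)))
  cat(sprintf("  polarization: onset %.2g+/-%.2g h, new-pole bias %.2g, focus fraction %.2g\n",
              object@polarization_onset_mean, object@polarization_onset_sd,
              object@new_pole_bias, object@focus_fraction))
  cat(sprintf("  noise: psf %.2g um, shot %s, read sd %.2g\n",
              object@psf_sigma, object@shot_noise, object@read_noise_sd))
})

setMethod("show", "PolarClassifier", function(object) {
  cat("PolarClassifier (logistic,", length(object@features), "features)\n")
  co <- object@coefficients
  for (i in seq_along(co))
    cat(sprintf("  %-22s %+.4f\n", names(co)[i], co[i]))
  cat("  threshold:", object@threshold, "\n")
})
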