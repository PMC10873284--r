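#' @import methods
NULL

#' Simulation configuration for a synthetic microcolony time lapse
#'
#' Holds every tunable parameter of the forward model: pad geometry, cell
#' geometry, growth and lag kinetics, arrest and release events, polar-focus
#' formation, and the rendering/noise model. Field names mirror the keys of
#' the YAML configuration file accepted by [readRunConfig()].
#'
#' Lengths are in micrometres, times in hours, rates per hour, and
#' fluorophore amounts in arbitrary photon counts. `periplasm_intensity` is
#' the photon budget per micrometre of cell length, so a cell's total
#' fluorophore is independent of how it happens to rasterize.
#'
#' @slot seed integer; master seed for all random draws.
#' @slot frame_interval hours between frames (default 0.5, i.e. 30 min).
#' @slot n_frames number of frames.
#' @slot pixel_size micrometres per pixel.
#' @slot cell_width cell diameter, micrometres.
#' @slot birth_length,division_length length at birth and at division, um.
#' @slot elongation_rate exponential rate on length, per hour.
#' @slot lag_duration_mean,lag_duration_sd founder lag duration, hours.
#' @slot carrying_capacity cell count at which the colony arrests.
#' @slot arrest_frame optional frame at which division arrest is imposed
#'   (a chemical stressor); `NA_integer_` for none.
#' @slot polarization_onset_mean,polarization_onset_sd hours after arrest
#'   until a cell forms a polar focus.
#' @slot new_pole_bias probability that the focus forms at the new pole.
#' @slot depolarization_delay_mean,depolarization_delay_sd hours after
#'   release until a polarized cell redistributes its fluorophore.
#' @slot release_frame optional frame simulating transfer to fresh medium;
#'   `NA_integer_` for none.
#' @slot initial_polarized fraction of founder cells polarized (and
#'   division-arrested) at acquisition start, emulating cells pre-treated
#'   with a stressor before inoculation.
#' @slot periplasm_intensity photons per um of cell length.
#' @slot focus_fraction fraction of a polarized cell's fluorophore in the focus.
#' @slot focus_sigma standard deviation of the polar focus, um.
#' @slot psf_sigma point-spread-function standard deviation, um.
#' @slot read_noise_sd additive Gaussian read noise, counts.
#' @slot shot_noise logical; Poisson-resample photon counts.
#' @slot producer logical; non-producers carry no intrinsic fluorophore.
#' @slot crossfeed logical; non-producers acquire cross-fed fluorophore.
#' @slot crossfeed_factor scale on the colony-mean level acquired by
#'   cross-fed non-producers.
#' @slot reporter logical; render a second periplasmic reporter channel
#'   sharing the pyoverdin channel's spatial distribution.
#' @slot reporter_intensity photons per um for the reporter channel.
#' @slot n_initial number of founder cells.
#' @slot placement founder placement: `"clustered"` (an inoculum spot that
#'   grows into one microcolony) or `"grid"` (a sparse regular field of
#'   isolated cells, for calibration scenarios).
#' @slot phase_intensity intensity scale of the phase-contrast-like channel.
#' @slot img_margin canvas margin around the colony, um.
#'
#' @seealso [simulationConfig()], [simulateColony()], [renderFrames()]
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    frame_interval = "numeric",
    n_frames = "integer",
    pixel_size = "numeric",
    cell_width = "numeric",
    birth_length = "numeric",
    division_length = "numeric",
    elongation_rate = "numeric",
    lag_duration_mean = "numeric",
    lag_duration_sd = "numeric",
    carrying_capacity = "integer",
    arrest_frame = "integer",
    polarization_onset_mean = "numeric",
    polarization_onset_sd = "numeric",
    new_pole_bias = "numeric",
    depolarization_delay_mean = "numeric",
    depolarization_delay_sd = "numeric",
    release_frame = "integer",
    initial_polarized = "numeric",
    periplasm_intensity = "numeric",
    focus_fraction = "numeric",
    focus_sigma = "numeric",
    psf_sigma = "numeric",
    read_noise_sd = "numeric",
    shot_noise = "logical",
    producer = "logical",
    crossfeed = "logical",
    crossfeed_factor = "numeric",
    reporter = "logical",
    reporter_intensity = "numeric",
    n_initial = "integer",
    placement = "character",
    phase_intensity = "numeric",
    img_margin = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("frame_interval", "pixel_size", "cell_width", "birth_length",
              "division_length", "elongation_rate", "lag_duration_mean",
              "lag_duration_sd", "polarization_onset_mean",
              "polarization_onset_sd", "new_pole_bias",
              "depolarization_delay_mean", "depolarization_delay_sd",
              "initial_polarized", "periplasm_intensity", "focus_fraction",
              "focus_sigma", "psf_sigma", "read_noise_sd", "crossfeed_factor",
              "reporter_intensity", "phase_intensity", "img_margin")) {
    if (!num1(slot(object, s)))
      msgs <- c(msgs, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msgs) == 0L) {
    if (object@birth_length >= object@division_length)
      msgs <- c(msgs, "birth_length must be < division_length")
    nonneg <- c("elongation_rate", "lag_duration_mean", "lag_duration_sd",
                "polarization_onset_mean", "polarization_onset_sd",
                "depolarization_delay_mean", "depolarization_delay_sd",
                "periplasm_intensity", "focus_sigma", "psf_sigma",
                "read_noise_sd", "crossfeed_factor", "reporter_intensity",
                "phase_intensity", "img_margin")
    bad <- nonneg[vapply(nonneg, function(s) slot(object, s) < 0, logical(1))]
    if (length(bad))
      msgs <- c(msgs, paste0("negative value for: ", paste(bad, collapse = ", ")))
    for (s in c("new_pole_bias", "focus_fraction", "initial_polarized")) {
      v <- slot(object, s)
      if (v < 0 || v > 1) msgs <- c(msgs, sprintf("'%s' must be in [0, 1]", s))
    }
    if (object@frame_interval <= 0) msgs <- c(msgs, "frame_interval must be > 0")
    if (object@pixel_size <= 0) msgs <- c(msgs, "pixel_size must be > 0")
    if (object@cell_width <= 0) msgs <- c(msgs, "cell_width must be > 0")
    if (object@n_frames < 1L) msgs <- c(msgs, "n_frames must be >= 1")
    if (object@carrying_capacity < 1L)
      msgs <- c(msgs, "carrying_capacity must be >= 1")
    if (object@n_initial < 1L) msgs <- c(msgs, "n_initial must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated microcolony
#'
#' Frame-by-frame state of every cell (position, orientation, length, growth
#' phase, polarization state, focus pole, fluorophore content) together with
#' the lineage table and the configuration that generated it. Used as the
#' oracle against which every measurement stage of the pipeline is tested.
#'
#' @slot cells data.frame, one row per cell per frame. Columns: `frame`
#'   (0-based), `id`, `parent`, `birth_frame`, `cx`, `cy` (pixel coordinates,
#'   0-based), `theta` (radians, axis angle in `[0, pi)`), `length_um`,
#'   `width_um`, `phase` (one of lag/exponential/stationary/arrested/
#'   released), `polarized`, `focus_pole` (new/old/none), `new_pole_x`,
#'   `new_pole_y` (unit vector from the cell centre towards the new pole),
#'   `total_fluorophore`.
#' @slot lineage data.frame, one row per cell: `id`, `parent`, `birth_frame`,
#'   `division_frame` (`NA` if the cell never divides).
#' @slot config the [SimulationConfig-class] that produced the truth.
#' @slot dims integer height/width (pixels) of the rendering canvas.
#'
#' @seealso [simulateColony()], [truthCells()], [truthLineage()]
#' @export
setClass("SimTruth",
  representation(
    cells = "data.frame",
    lineage = "data.frame",
    config = "SimulationConfig",
    dims = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msgs <- character(0)
  need <- c("frame", "id", "parent", "birth_frame", "cx", "cy", "theta",
            "length_um", "width_um", "phase", "polarized", "focus_pole",
            "new_pole_x", "new_pole_y", "total_fluorophore")
  if (!all(need %in% names(object@cells)))
    msgs <- c(msgs, "cells table is missing required columns")
  lin <- object@lineage
  if (!all(c("id", "parent", "birth_frame", "division_frame") %in% names(lin)))
    msgs <- c(msgs, "lineage table is missing required columns")
  if (length(msgs) == 0L && nrow(lin)) {
    kids <- table(lin$parent[!is.na(lin$parent)])
    if (any(kids > 2)) msgs <- c(msgs, "a cell has more than two daughters")
    ok <- is.na(lin$division_frame) | is.na(lin$birth_frame) |
      lin$division_frame >= lin$birth_frame
    if (!all(ok)) msgs <- c(msgs, "division before birth in lineage")
    ex <- object@cells$phase == "exponential" & object@cells$polarized
    if (any(ex)) msgs <- c(msgs, "polarized cell in exponential phase")
  }
  if (length(msgs)) msgs else TRUE
})

#' A multi-channel time-lapse image stack
#'
#' Thin container for registered 2D frames: one `height x width x n_frames`
#' numeric array per channel, plus the acquisition metadata every downstream
#' computation needs (frame interval, pixel size).
#'
#' @slot data named list of 3D numeric arrays, one per channel, identical dims.
#' @slot channels channel names, in the order of `data`.
#' @slot frame_interval hours between frames.
#' @slot pixel_size micrometres per pixel.
#'
#' @seealso [frameStack()], [stackFrame()], [renderFrames()], [readFrameStack()]
#' @export
setClass("FrameStack",
  representation(
    data = "list",
    channels = "character",
    frame_interval = "numeric",
    pixel_size = "numeric"
  )
)

setValidity("FrameStack", function(object) {
  msgs <- character(0)
  if (length(object@data) < 1L) msgs <- c(msgs, "at least one channel required")
  if (!identical(names(object@data), object@channels))
    msgs <- c(msgs, "channel names must match names(data)")
  dims <- lapply(object@data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msgs <- c(msgs, "each channel must be a 3D array (y, x, frame)")
  else if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msgs <- c(msgs, "all channels must share dimensions")
  if (length(object@frame_interval) != 1L || !is.finite(object@frame_interval) ||
      object@frame_interval <= 0)
    msgs <- c(msgs, "frame_interval must be a single positive number")
  if (length(object@pixel_size) != 1L || !is.finite(object@pixel_size) ||
      object@pixel_size <= 0)
    msgs <- c(msgs, "pixel_size must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Logistic polarized/homogeneous cell classifier
#'
#' A fitted logistic discriminant on three per-cell features: the maximum
#' pole/centre intensity ratio, the long-axis profile peak-to-median ratio,
#' and the fraction of total cell intensity falling in the brightest pole
#' third. Cells scoring above `threshold` are labelled "polarized".
#'
#' @slot coefficients named numeric: intercept plus one coefficient per feature.
#' @slot features feature column names, in coefficient order.
#' @slot threshold posterior-probability decision threshold.
#'
#' @seealso [fitClassifier()], [classifyCells()], [defaultClassifier()]
#' @export
setClass("PolarClassifier",
  representation(
    coefficients = "numeric",
    features = "character",
    threshold = "numeric"
  )
)

setValidity("PolarClassifier", function(object) {
  msgs <- character(0)
  if (length(object@coefficients) != length(object@features) + 1L)
    msgs <- c(msgs, "need one coefficient per feature plus an intercept")
  if (any(!is.finite(object@coefficients)))
    msgs <- c(msgs, "coefficients must be finite")
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    msgs <- c(msgs, "threshold must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})
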