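# TIFF / CSV / YAML interchange. Intensity stacks are written as 16-bit
# multi-page TIFF (lossless for integer counts up to 65535), label images as
# 16-bit TIFF, tables as CSV with schema validation on read.

.tiffEncode <- function(m) {
  m[m < 0] <- 0
  m[m > 65535] <- 65535
  round(m) / 65535
}

#' Write / read an intensity stack as multi-page 16-bit TIFF
#'
#' One file per channel, named `<prefix><channel>.tif`. Counts are rounded
#' and clipped to the 16-bit range; the round trip is lossless for integer
#' data in range.
#'
#' @param stack a [FrameStack-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `writeFrameStack`: invisible named vector of file paths.
#' @export
writeFrameStack <- function(stack, dir, prefix = "stack_") {
  stopifnot(is(stack, "FrameStack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in channelNames(stack)) {
    d <- stack@data[[ch]]
    pages <- lapply(seq_len(dim(d)[3]), function(f) .tiffEncode(d[, , f]))
    p <- file.path(dir, paste0(prefix, ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths[ch] <- p
  }
  invisible(paths)
}

#' @rdname writeFrameStack
#' @param paths named character vector: channel name -> TIFF path.
#' @param frame_interval,pixel_size acquisition metadata.
#' @return `readFrameStack`: a [FrameStack-class] with counts restored.
#' @export
readFrameStack <- function(paths, frame_interval, pixel_size) {
  data <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    simplify2array(lapply(pages, function(m) round(m * 65535)))
  })
  names(data) <- names(paths)
  frameStack(data, frame_interval, pixel_size)
}

#' Write / read a label stack as multi-page 16-bit TIFF
#'
#' @param labels integer array (`height x width x n_frames`), ids < 65536.
#' @param path TIFF file path.
#' @return `readLabelStack`: an integer array.
#' @export
writeLabelStack <- function(labels, path) {
  stopifnot(length(dim(labels)) == 3L)
  if (max(labels) > 65535L) stop("label ids exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(f) labels[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelStack
#' @export
readLabelStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(lapply(pages, function(m) round(m * 65535)))
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  storage.mode(arr) <- "integer"
  arr
}

# Versioned CSV schemas, validated on read.
.schemas <- list(
  cells = c("frame", "cell_id", "area", "cx", "cy", "orientation",
            "axis_length_um", "width_um", "solidity", "qc_flag"),
  profiles = c("cell_id", "frame", "bin", "position", "intensity",
               "interpolated"),
  polarization = c("cell_id", "frame", "ratio_a", "ratio_b", "ratio_new",
                   "ratio_old", "max_ratio", "peak_med", "pole_frac",
                   "score", "label", "excluded"),
  frequency = c("frame", "time_h", "n", "n_polarized", "fraction"),
  tracks = c("track_id", "frame", "cell_id", "age_h"),
  lineage = c("track_id", "parent", "birth_frame", "division_frame"),
  lag = c("track_id", "condition", "lag_h", "censored", "horizon_h")
)

#' Write / read a pipeline table as CSV with schema validation
#'
#' @param df table to write.
#' @param path CSV path.
#' @param schema schema name (one of `names(polarTrack:::.schemas)`), used
#'   to check required columns on read.
#' @return `readTable`: the validated data.frame.
#' @export
writeTable <- function(df, path, schema = NULL) {
  if (!is.null(schema)) {
    need <- .schemas[[schema]]
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("table does not satisfy schema '", schema, "': missing ",
           paste(miss, collapse = ", "))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    need <- .schemas[[schema]]
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("file ", path, " does not satisfy schema '", schema,
           "': missing ", paste(miss, collapse = ", "))
  }
  df
}

# Allowed keys of the run configuration file.
.runConfigKeys <- list(
  top = c("seed", "frame_interval", "pixel_size", "channels", "log_level",
          "paths", "simulate", "segmentation", "profiles", "polarization",
          "lineage", "kinetics"),
  segmentation = c("channel", "sigma", "min_area", "tolerance", "ext",
                   "solidity_min", "aspect_iso", "use_truth_labels"),
  profiles = c("n_bins", "smoothing_window", "background", "channel"),
  polarization = c("channel", "background", "n_bins", "model"),
  lineage = c("iou_min", "gap_close"),
  kinetics = c("k_persistence", "min_uncensored")
)

#' Read and validate a run configuration (YAML)
#'
#' Top level: `seed`, `frame_interval`, `pixel_size`, `channels`,
#' `log_level`, plus per-module parameter blocks (`simulate` mirrors
#' [SimulationConfig-class] field names exactly; `segmentation`, `profiles`,
#' `polarization`, `lineage`, `kinetics` hold the corresponding function
#' arguments). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return named list of validated configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .runConfigKeys$top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (block in intersect(names(cfg), names(.runConfigKeys))) {
    if (block == "top") next
    unknown <- setdiff(names(cfg[[block]]), .runConfigKeys[[block]])
    if (length(unknown))
      stop("unknown key(s) in '", block, "' block: ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$simulate)) {
    # constructor validates names and values
    do.call(simulationConfig,
            c(list(seed = if (!is.null(cfg$seed)) cfg$seed else 1L),
              cfg$simulate))
  }
  cfg
}
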