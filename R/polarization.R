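#' Partition a cell mask into pole / centre / pole axial thirds
#'
#' Normalizes the axial coordinate of every mask pixel to `[0, 1]` along the
#' principal axis and assigns pixels with coordinate in `[0, 1/3)` to pole A,
#' `[1/3, 2/3)` to the centre, and `[2/3, 1]` to pole B. The partition is
#' exact: every pixel belongs to exactly one region. Pole A is the end with
#' the smaller projection onto the axis unit vector (angle in `[0, pi)`).
#'
#' @param x,y 0-based pixel coordinates of the mask.
#' @param orientation optional axis angle; default principal axis.
#' @return list with integer index vectors `pole_a`, `center`, `pole_b`
#'   (into `x`/`y`), the axis unit vector `u`, centre `ctr`, and the
#'   normalized axial coordinate `t`.
#' @export
partitionThirds <- function(x, y, orientation = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (is.null(orientation)) {
    pa <- principalAxis(x, y)
    u <- c(pa$ux, pa$uy); ctr <- c(pa$cx, pa$cy)
  } else {
    u <- c(cos(orientation), sin(orientation))
    ctr <- c(mean(x), mean(y))
  }
  proj <- (x - ctr[1]) * u[1] + (y - ctr[2]) * u[2]
  rng <- range(proj)
  if (diff(rng) < 1e-9) stop("degenerate axis: zero projection variance")
  t <- (proj - rng[1]) / diff(rng)
  list(pole_a = which(t < 1 / 3),
       center = which(t >= 1 / 3 & t < 2 / 3),
       pole_b = which(t >= 2 / 3),
       u = u, ctr = ctr, t = t)
}

#' Pole/centre intensity ratios
#'
#' The core accumulation statistic: the sum of pixel intensities in each
#' outer axial third divided by the sum in the middle third. Raw sums, no
#' area normalization (an area-normalized variant is available via
#' `normalize = TRUE`).
#'
#' @param partition result of [partitionThirds()].
#' @param intensity pixel intensities aligned with the partition's pixels.
#' @param normalize divide each region sum by its pixel count first.
#' @return named numeric: `ratio_a`, `ratio_b`.
#' @export
poleCenterRatio <- function(partition, intensity, normalize = FALSE) {
  sa <- sum(intensity[partition$pole_a])
  sc <- sum(intensity[partition$center])
  sb <- sum(intensity[partition$pole_b])
  if (normalize) {
    sa <- sa / max(length(partition$pole_a), 1L)
    sc <- sc / max(length(partition$center), 1L)
    sb <- sb / max(length(partition$pole_b), 1L)
  }
  if (!is.finite(sc) || sc <= 0)
    stop("non-positive centre intensity sum; cell must be excluded")
  c(ratio_a = sa / sc, ratio_b = sb / sc)
}

# classifier feature vector for one cell
.polFeatures <- function(x, y, intensity, orientation = NULL,
                         n_bins = 20L) {
  part <- partitionThirds(x, y, orientation)
  r <- poleCenterRatio(part, intensity)
  prof <- axisProfile(x, y, intensity, n_bins = n_bins,
                      orientation = orientation)
  med <- stats::median(prof$intensity)
  peak <- if (med > 0) max(prof$intensity) / med else 1
  tot <- sum(intensity)
  pf <- if (tot > 0)
    max(sum(intensity[part$pole_a]), sum(intensity[part$pole_b])) / tot
  else 1 / 3
  c(max_ratio = unname(max(r)), peak_med = peak, pole_frac = pf,
    ratio_a = unname(r["ratio_a"]), ratio_b = unname(r["ratio_b"]))
}

#' Fit the polarized/homogeneous classifier
#'
#' Logistic discriminant on three per-cell features: maximum pole/centre
#' ratio, long-axis profile peak-to-median ratio, and the fraction of total
#' cell intensity in the brightest pole third. The fit is a deterministic
#' maximum-likelihood logistic regression; permuting training rows does not
#' change the decision boundary.
#'
#' @param features data.frame with columns `max_ratio`, `peak_med`,
#'   `pole_frac`.
#' @param labels logical (TRUE = polarized) or character
#'   ("polarized"/"homogeneous"), one per row.
#' @param threshold posterior decision threshold.
#' @return a [PolarClassifier-class].
#' @export
fitClassifier <- function(features, labels, threshold = 0.5) {
  feats <- c("max_ratio", "peak_med", "pole_frac")
  stopifnot(all(feats %in% names(features)))
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "polarized"
  if (length(unique(labels)) < 2L)
    stop("training set must contain both polarized and homogeneous cells")
  df <- features[feats]
  df$.y <- as.numeric(labels)
  fit <- suppressWarnings(
    stats::glm(.y ~ max_ratio + peak_med + pole_frac, data = df,
               family = stats::binomial()))
  co <- stats::coef(fit)
  co[!is.finite(co)] <- 0
  new("PolarClassifier", coefficients = co, features = feats,
      threshold = threshold)
}

#' Classify cells as polarized or homogeneous
#'
#' @param classifier a [PolarClassifier-class].
#' @param features data.frame containing the classifier's feature columns.
#' @return data.frame: `score` (posterior probability of "polarized") and
#'   `label`.
#' @export
classifyCells <- function(classifier, features) {
  stopifnot(is(classifier, "PolarClassifier"))
  X <- as.matrix(cbind(1, features[classifier@features]))
  eta <- drop(X %*% classifier@coefficients)
  p <- 1 / (1 + exp(-eta))
  data.frame(score = p,
             label = ifelse(p > classifier@threshold, "polarized",
                            "homogeneous"))
}

#' Write / read a classifier as a plain-text coefficient file
#'
#' @param classifier a [PolarClassifier-class].
#' @param path file path.
#' @return `readClassifier` returns a [PolarClassifier-class];
#'   `writeClassifier` returns `path` invisibly.
#' @export
writeClassifier <- function(classifier, path) {
  lines <- c("# polarTrack logistic classifier v1",
             sprintf("threshold\t%.17g", classifier@threshold),
             sprintf("%s\t%.17g", names(classifier@coefficients),
                     classifier@coefficients))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  keys <- vapply(parts, `[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[`, "", 2L))
  th <- vals[keys == "threshold"]
  co <- vals[keys != "threshold"]
  names(co) <- keys[keys != "threshold"]
  new("PolarClassifier", coefficients = co,
      features = setdiff(names(co), "(Intercept)"), threshold = th)
}

#' The default classifier shipped with the package
#'
#' Trained on simulator output with known polarization states under a fixed
#' seed (see `inst/scripts/make_default_classifier.R`).
#'
#' @return a [PolarClassifier-class].
#' @export
defaultClassifier <- function() {
  readClassifier(system.file("extdata", "polar_classifier_default.txt",
                             package = "polarTrack", mustWork = TRUE))
}

#' Per-cell polarization records for a stack
#'
#' For every qc-ok cell: pole/centre ratios per pole, classifier features,
#' score and label; when pole identity is supplied, ratios mapped to the
#' new and old pole. Cells whose centre intensity sum is non-positive are
#' flagged (`excluded = TRUE`) and left unlabelled.
#'
#' @param labels label array.
#' @param stack a [FrameStack-class].
#' @param cells observation table from [measureStack()].
#' @param classifier a [PolarClassifier-class]; default the shipped model.
#' @param channel intensity channel.
#' @param background `"median"` (per-frame median subtraction) or `"none"`.
#' @param n_bins profile bins for the peak-to-median feature.
#' @param poleSigns optional data.frame (`frame`, `cell_id`,
#'   `new_pole_sign`) from [poleIdentity()]: sign +1 means the new pole is
#'   the axis end with the larger projection (pole B).
#' @return data.frame: `cell_id`, `frame`, `ratio_a`, `ratio_b`,
#'   `ratio_new`, `ratio_old`, `max_ratio`, `peak_med`, `pole_frac`,
#'   `score`, `label`, `excluded`.
#' @export
quantifyPolarization <- function(labels, stack, cells, classifier = NULL,
                                 channel = "pvd",
                                 background = c("median", "none"),
                                 n_bins = 20L, poleSigns = NULL) {
  background <- match.arg(background)
  if (is.null(classifier)) classifier <- defaultClassifier()
  ok <- cells[cells$qc_flag == "ok", , drop = FALSE]
  rows <- list()
  for (f in sort(unique(ok$frame))) {
    img <- stackFrame(stack, channel, f + 1L)
    if (background == "median") {
      img <- img - stats::median(img)
      img[img < 0] <- 0
    }
    sub <- ok[ok$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      px <- cellPixels(labels, f, sub$cell_id[i])
      ints <- img[px$idx]
      rec <- data.frame(cell_id = sub$cell_id[i], frame = f,
                        ratio_a = NA_real_, ratio_b = NA_real_,
                        ratio_new = NA_real_, ratio_old = NA_real_,
                        max_ratio = NA_real_, peak_med = NA_real_,
                        pole_frac = NA_real_, score = NA_real_,
                        label = NA_character_, excluded = FALSE,
                        stringsAsFactors = FALSE)
      ft <- tryCatch(
        .polFeatures(px$x, px$y, ints,
                     orientation = sub$orientation[i], n_bins = n_bins),
        error = function(e) NULL)
      if (is.null(ft)) {
        rec$excluded <- TRUE
      } else {
        rec$ratio_a <- ft["ratio_a"]; rec$ratio_b <- ft["ratio_b"]
        rec$max_ratio <- ft["max_ratio"]; rec$peak_med <- ft["peak_med"]
        rec$pole_frac <- ft["pole_frac"]
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  good <- !out$excluded
  if (any(good)) {
    cl <- classifyCells(classifier, out[good, , drop = FALSE])
    out$score[good] <- cl$score
    out$label[good] <- cl$label
  }
  if (!is.null(poleSigns)) {
    key <- paste(out$frame, out$cell_id)
    pk <- paste(poleSigns$frame, poleSigns$cell_id)
    m <- match(key, pk)
    sgn <- poleSigns$new_pole_sign[m]
    newIsB <- !is.na(sgn) & sgn > 0
    newIsA <- !is.na(sgn) & sgn < 0
    out$ratio_new[newIsB] <- out$ratio_b[newIsB]
    out$ratio_old[newIsB] <- out$ratio_a[newIsB]
    out$ratio_new[newIsA] <- out$ratio_a[newIsA]
    out$ratio_old[newIsA] <- out$ratio_b[newIsA]
  }
  out
}

#' Fraction of polarized cells per frame
#'
#' @param records polarization table from [quantifyPolarization()].
#' @param frame_interval hours per frame, for the `time_h` column.
#' @return data.frame: `frame`, `time_h`, `n`, `n_polarized`, `fraction`.
#' @export
polarizedFrequency <- function(records, frame_interval = 0.5) {
  rec <- records[!is.na(records$label), , drop = FALSE]
  if (nrow(rec) == 0L) {
    warning("no classified cells; frequency undefined")
    return(data.frame(frame = integer(0), time_h = numeric(0),
                      n = integer(0), n_polarized = integer(0),
                      fraction = numeric(0)))
  }
  frames <- sort(unique(rec$frame))
  n <- vapply(frames, function(f) sum(rec$frame == f), integer(1))
  np <- vapply(frames, function(f)
    sum(rec$frame == f & rec$label == "polarized"), integer(1))
  data.frame(frame = frames, time_h = frames * frame_interval,
             n = n, n_polarized = np, fraction = np / n)
}

#' Per-pole ratio pairs for two channels
#'
#' Compares, cell by cell and pole by pole, the pole/centre ratio measured
#' in two channels on identical masks and partitions (the co-localization
#' analysis for a second periplasmic reporter). Also reports the Pearson
#' correlation of the log-ratios.
#'
#' @param labels label array.
#' @param stack a [FrameStack-class] containing both channels.
#' @param cells observation table.
#' @param channels length-2 character vector of channel names.
#' @param background per-frame background handling as in
#'   [quantifyPolarization()].
#' @param poleSigns optional pole-identity table (see
#'   [quantifyPolarization()]); when given, the output `pole` column is
#'   "new"/"old" instead of "a"/"b".
#' @return data.frame: `cell_id`, `frame`, `pole`, `ratio_1`, `ratio_2`,
#'   with the log-ratio Pearson correlation in `attr(, "correlation")`.
#' @export
channelRatioPairs <- function(labels, stack, cells, channels,
                              background = c("median", "none"),
                              poleSigns = NULL) {
  background <- match.arg(background)
  stopifnot(length(channels) == 2L)
  missing <- setdiff(channels, channelNames(stack))
  if (length(missing))
    stop("channel(s) not in stack: ", paste(missing, collapse = ", "))
  ok <- cells[cells$qc_flag == "ok", , drop = FALSE]
  rows <- list()
  for (f in sort(unique(ok$frame))) {
    imgs <- lapply(channels, function(ch) {
      img <- stackFrame(stack, ch, f + 1L)
      if (background == "median") {
        img <- img - stats::median(img)
        img[img < 0] <- 0
      }
      img
    })
    sub <- ok[ok$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      px <- cellPixels(labels, f, sub$cell_id[i])
      part <- tryCatch(
        partitionThirds(px$x, px$y, orientation = sub$orientation[i]),
        error = function(e) NULL)
      if (is.null(part)) next
      r1 <- tryCatch(poleCenterRatio(part, imgs[[1]][px$idx]),
                     error = function(e) NULL)
      r2 <- tryCatch(poleCenterRatio(part, imgs[[2]][px$idx]),
                     error = function(e) NULL)
      if (is.null(r1) || is.null(r2)) next
      poles <- c("a", "b")
      if (!is.null(poleSigns)) {
        m <- which(poleSigns$frame == f &
                     poleSigns$cell_id == sub$cell_id[i])
        if (length(m) == 1L && !is.na(poleSigns$new_pole_sign[m]))
          poles <- if (poleSigns$new_pole_sign[m] > 0)
            c("old", "new") else c("new", "old")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = sub$cell_id[i], frame = f, pole = poles,
        ratio_1 = unname(r1), ratio_2 = unname(r2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out) && nrow(out) > 2L &&
      stats::sd(log(out$ratio_1)) > 0 && stats::sd(log(out$ratio_2)) > 0) {
    attr(out, "correlation") <- stats::cor(log(out$ratio_1),
                                           log(out$ratio_2))
  } else {
    attr(out, "correlation") <- NA_real_
  }
  out
}

#' Classifier features with ground-truth labels from a simulation
#'
#' Measures every qc-ok cell of a simulated, rendered colony on its
#' ground-truth label images and returns the classifier feature vector
#' together with the true polarization state — the labelled training/test
#' material for [fitClassifier()].
#'
#' @param sim result of [simulateStack()].
#' @param channel intensity channel.
#' @param background background handling as in [quantifyPolarization()].
#' @param n_bins profile bins for the peak-to-median feature.
#' @return data.frame: `frame`, `cell_id`, `max_ratio`, `peak_med`,
#'   `pole_frac`, `polarized` (logical truth).
#' @export
truthFeatures <- function(sim, channel = "pvd",
                          background = c("median", "none"), n_bins = 20L) {
  background <- match.arg(background)
  cells <- measureStack(sim$labels, sim$stack)
  ok <- cells[cells$qc_flag == "ok", , drop = FALSE]
  tc <- truthCells(sim$truth)
  tkey <- paste(tc$frame, tc$id)
  rows <- list()
  for (f in sort(unique(ok$frame))) {
    img <- stackFrame(sim$stack, channel, f + 1L)
    if (background == "median") {
      img <- img - stats::median(img)
      img[img < 0] <- 0
    }
    sub <- ok[ok$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      px <- cellPixels(sim$labels, f, sub$cell_id[i])
      ft <- tryCatch(
        .polFeatures(px$x, px$y, img[px$idx],
                     orientation = sub$orientation[i], n_bins = n_bins),
        error = function(e) NULL)
      if (is.null(ft)) next
      m <- match(paste(f, sub$cell_id[i]), tkey)
      if (is.na(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, cell_id = sub$cell_id[i],
        max_ratio = unname(ft["max_ratio"]),
        peak_med = unname(ft["peak_med"]),
        pole_frac = unname(ft["pole_frac"]),
        polarized = tc$polarized[m])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
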