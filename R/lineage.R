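# Frame-to-frame tracking, division detection, generation labels, pole
# identity, elongation rates, and colony age curves.

# Overlap table between two label matrices: data.frame(a, b, inter, iou).
.overlapTable <- function(la, lb) {
  sel <- la > 0L & lb > 0L
  if (!any(sel))
    return(data.frame(a = integer(0), b = integer(0), inter = integer(0),
                      iou = numeric(0)))
  tab <- table(la[sel], lb[sel])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("a", "b", "inter")
  df <- df[df$inter > 0L, , drop = FALSE]
  df$a <- as.integer(df$a); df$b <- as.integer(df$b)
  areaA <- tabulate(la)
  areaB <- tabulate(lb)
  df$iou <- df$inter / (areaA[df$a] + areaB[df$b] - df$inter)
  df
}

.centroids <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(NULL)
  H <- nrow(lab)
  ids <- lab[idx]
  x <- (idx - 1L) %/% H
  y <- (idx - 1L) %% H
  data.frame(id = sort(unique(ids)),
             cx = tapply(x, ids, mean)[as.character(sort(unique(ids)))],
             cy = tapply(y, ids, mean)[as.character(sort(unique(ids)))])
}

# Match the masks of two consecutive frames.
#
# 1. Accept confident mutual-best continuations (IoU >= conf_iou; a
#    mother/daughter pair cannot exceed ~0.55 at the simulator's division
#    asymmetry, so these are unambiguous).
# 2. Estimate a local displacement field from them (inverse-distance
#    weighting of the confident centroid shifts) to predict where each
#    remaining mask should now sit.
# 3. Let single-continuation and daughter-pair hypotheses compete greedily:
#    score = (union) IoU x a Gaussian penalty on the distance between the
#    flow-predicted mother centroid and the candidate (pair) centroid, with
#    area-ratio plausibility windows (a daughter is roughly half her mother;
#    a continuation is not). Hypotheses below iou_min are never accepted.
.matchFrames <- function(la, lb, iou_min = 0.3, conf_iou = 0.65, sig = 6,
                         rounds = 3L) {
  areaA <- tabulate(la); areaB <- tabulate(lb)
  tab <- .overlapTable(la, lb)
  ca <- .centroids(la); cb <- .centroids(lb)
  idsA <- if (is.null(ca)) integer(0) else ca$id
  idsB <- if (is.null(cb)) integer(0) else cb$id
  caX <- stats::setNames(ca$cx, ca$id); caY <- stats::setNames(ca$cy, ca$id)
  cbX <- stats::setNames(cb$cx, cb$id); cbY <- stats::setNames(cb$cy, cb$id)
  usedA <- integer(0); usedB <- integer(0)
  cont <- NULL; divs <- NULL
  H <- nrow(la); W <- ncol(la)

  cf <- tab[tab$iou >= conf_iou, , drop = FALSE]
  cf <- cf[order(-cf$iou), , drop = FALSE]
  for (k in seq_len(nrow(cf))) {
    if (cf$a[k] %in% usedA || cf$b[k] %in% usedB) next
    usedA <- c(usedA, cf$a[k]); usedB <- c(usedB, cf$b[k])
    cont <- rbind(cont, data.frame(a = cf$a[k], b = cf$b[k]))
  }

  # displacement field anchored on every accepted match; division anchors use
  # the daughter-pair centroid
  makeFlow <- function() {
    fx <- numeric(0); fy <- numeric(0); dx <- numeric(0); dy <- numeric(0)
    if (!is.null(cont) && nrow(cont)) {
      fx <- c(fx, caX[as.character(cont$a)])
      fy <- c(fy, caY[as.character(cont$a)])
      dx <- c(dx, cbX[as.character(cont$b)] - caX[as.character(cont$a)])
      dy <- c(dy, cbY[as.character(cont$b)] - caY[as.character(cont$a)])
    }
    if (!is.null(divs) && nrow(divs)) {
      w1 <- areaB[divs$b1]; w2 <- areaB[divs$b2]
      pcx <- (cbX[as.character(divs$b1)] * w1 +
                cbX[as.character(divs$b2)] * w2) / (w1 + w2)
      pcy <- (cbY[as.character(divs$b1)] * w1 +
                cbY[as.character(divs$b2)] * w2) / (w1 + w2)
      fx <- c(fx, caX[as.character(divs$a)])
      fy <- c(fy, caY[as.character(divs$a)])
      dx <- c(dx, pcx - caX[as.character(divs$a)])
      dy <- c(dy, pcy - caY[as.character(divs$a)])
    }
    if (!length(fx)) return(function(x0, y0) c(0, 0))
    function(x0, y0) {
      d2 <- (fx - x0)^2 + (fy - y0)^2
      near <- order(d2)[seq_len(min(5L, length(d2)))]
      w <- 1 / (d2[near] + 25)
      c(sum(w * dx[near]) / sum(w), sum(w * dy[near]) / sum(w))
    }
  }

  # overlap table for the remaining masks: better of raw overlap and overlap
  # after shifting each mask (independently) by its flow-predicted motion
  remTable <- function(flow) {
    remA <- setdiff(idsA, usedA)
    rows <- list()
    for (id in remA) {
      idx <- which(la == id)
      p <- flow(caX[as.character(id)], caY[as.character(id)])
      wx <- round((idx - 1L) %/% H + p[1])
      wy <- round((idx - 1L) %% H + p[2])
      okp <- wx >= 0 & wx < W & wy >= 0 & wy < H
      if (any(okp)) {
        hits <- lb[wx[okp] * H + wy[okp] + 1L]
        hits <- hits[hits > 0L]
        if (length(hits)) {
          cnt <- table(hits)
          b <- as.integer(names(cnt)); inter <- as.integer(cnt)
          rows[[length(rows) + 1L]] <- data.frame(
            a = id, b = b, inter = inter,
            iou = inter / (length(idx) + areaB[b] - inter),
            shift_x = p[1], shift_y = p[2])
        }
      }
    }
    raw <- tab[tab$a %in% remA, , drop = FALSE]
    if (nrow(raw)) { raw$shift_x <- 0; raw$shift_y <- 0 }
    comb <- rbind(raw, if (length(rows)) do.call(rbind, rows))
    if (is.null(comb) || !nrow(comb)) return(comb)
    comb <- comb[order(paste(comb$a, comb$b), -comb$iou), , drop = FALSE]
    comb[!duplicated(paste(comb$a, comb$b)), , drop = FALSE]
  }

  buildHyp <- function(wtab, flow) {
    hyp <- list()
    for (a in setdiff(idsA, usedA)) {
      tb <- wtab[wtab$a == a & !(wtab$b %in% usedB), , drop = FALSE]
      if (is.null(tb) || nrow(tb) == 0L) next
      fl <- flow(caX[as.character(a)], caY[as.character(a)])
      pax <- caX[as.character(a)] + fl[1]
      pay <- caY[as.character(a)] + fl[2]
      for (i in seq_len(nrow(tb))) {
        b <- tb$b[i]; r <- areaB[b] / areaA[a]
        if (r < 0.72 || r > 1.8) next
        d2 <- (cbX[as.character(b)] - pax)^2 + (cbY[as.character(b)] - pay)^2
        hyp[[length(hyp) + 1L]] <- data.frame(
          type = "cont", a = a, b1 = b, b2 = NA_integer_,
          iou = tb$iou[i], score = tb$iou[i] * exp(-d2 / (2 * sig^2)))
      }
      if (nrow(tb) >= 2L) {
        tb2 <- tb[order(-tb$inter), ][seq_len(min(4L, nrow(tb))), ]
        for (i in 1:(nrow(tb2) - 1L)) for (j in (i + 1L):nrow(tb2)) {
          b1 <- tb2$b[i]; b2 <- tb2$b[j]
          r1 <- areaB[b1] / areaA[a]; r2 <- areaB[b2] / areaA[a]
          if (max(r1, r2) > 0.85 || r1 + r2 < 0.8 || r1 + r2 > 1.8) next
          inter <- tb2$inter[i] + tb2$inter[j]
          uIoU <- inter / (areaA[a] + areaB[b1] + areaB[b2] - inter)
          if (uIoU < iou_min) next
          pcx <- (cbX[as.character(b1)] * areaB[b1] +
                    cbX[as.character(b2)] * areaB[b2]) /
            (areaB[b1] + areaB[b2])
          pcy <- (cbY[as.character(b1)] * areaB[b1] +
                    cbY[as.character(b2)] * areaB[b2]) /
            (areaB[b1] + areaB[b2])
          d2 <- (pcx - pax)^2 + (pcy - pay)^2
          hyp[[length(hyp) + 1L]] <- data.frame(
            type = "div", a = a, b1 = b1, b2 = b2,
            iou = uIoU, score = uIoU * exp(-d2 / (2 * sig^2)))
        }
      }
    }
    if (!length(hyp)) return(NULL)
    do.call(rbind, hyp)
  }

  runRound <- function(defer) {
    flow <- makeFlow()
    wtab <- remTable(flow)
    hd <- buildHyp(wtab, flow)
    if (is.null(hd)) return(0L)
    hd <- hd[hd$iou >= iou_min, , drop = FALSE]
    hd <- hd[order(-hd$score), , drop = FALSE]
    accepted <- 0L
    # a division pair may not claim a mask that another unmatched cell of
    # continuation-compatible size half-explains
    stolenCont <- function(a, b) {
      alt <- wtab[wtab$b == b & wtab$a != a & !(wtab$a %in% usedA), ,
                  drop = FALSE]
      if (!nrow(alt)) return(FALSE)
      r <- areaB[b] / areaA[alt$a]
      alt <- alt[r >= 0.72 & r <= 1.8, , drop = FALSE]
      if (!nrow(alt)) return(FALSE)
      own <- wtab$inter[wtab$a == a & wtab$b == b]
      max(alt$inter) >= 0.5 * max(own, 1)
    }
    # defer any claim on a mask that another unmatched cell explains better;
    # the competitor is matched first in a later round (or not at all, in
    # which case the final unconstrained round settles it)
    outContributed <- function(a, bs) {
      for (b in bs) {
        own <- wtab$inter[wtab$a == a & wtab$b == b]
        alt <- wtab$inter[wtab$b == b & wtab$a != a &
                            !(wtab$a %in% usedA)]
        if (length(alt) && max(alt) > max(own, 0)) return(TRUE)
      }
      FALSE
    }
    for (k in seq_len(nrow(hd))) {
      h <- hd[k, ]
      if (h$a %in% usedA || h$b1 %in% usedB ||
          (!is.na(h$b2) && h$b2 %in% usedB)) next
      if (defer) {
        bs <- c(h$b1, if (!is.na(h$b2)) h$b2)
        if (outContributed(h$a, bs)) next
        if (h$type == "div" &&
            (stolenCont(h$a, h$b1) || stolenCont(h$a, h$b2))) next
      }
      if (h$type == "cont") {
        cont <<- rbind(cont, data.frame(a = h$a, b = h$b1))
        usedB <<- c(usedB, h$b1)
      } else {
        divs <<- rbind(divs, data.frame(a = h$a, b1 = h$b1, b2 = h$b2))
        usedB <<- c(usedB, h$b1, h$b2)
      }
      usedA <<- c(usedA, h$a)
      accepted <- accepted + 1L
    }
    accepted
  }

  for (rd in seq_len(rounds)) {
    if (runRound(defer = TRUE) == 0L) break
    if (length(setdiff(idsA, usedA)) == 0L) break
  }
  # final unconstrained round settles mutually-deferred claims
  if (length(setdiff(idsA, usedA))) runRound(defer = FALSE)

  # rescue: exclusive mutual-best continuations at low overlap, for cells
  # that moved more than their width between frames
  flow <- makeFlow()
  wtab <- remTable(flow)
  if (!is.null(wtab) && nrow(wtab)) {
    wtab <- wtab[!(wtab$b %in% usedB) & wtab$iou >= 0.08, , drop = FALSE]
    repeat {
      if (!nrow(wtab)) break
      wtab <- wtab[order(-wtab$iou), , drop = FALSE]
      h <- wtab[1, ]
      bestForA <- wtab$b[wtab$a == h$a][1]
      bestForB <- wtab$a[wtab$b == h$b][1]
      wtab <- wtab[-1, , drop = FALSE]
      r <- areaB[h$b] / areaA[h$a]
      if (bestForA == h$b && bestForB == h$a && r >= 0.72 && r <= 1.8 &&
          !(h$a %in% usedA) && !(h$b %in% usedB)) {
        cont <- rbind(cont, data.frame(a = h$a, b = h$b))
        usedA <- c(usedA, h$a); usedB <- c(usedB, h$b)
        wtab <- wtab[wtab$a != h$a & wtab$b != h$b, , drop = FALSE]
      }
    }
  }

  list(cont = cont, divs = divs,
       newB = setdiff(idsB, usedB), lostA = setdiff(idsA, usedA))
}

#' Track cells across frames of a label stack
#'
#' Greedy bipartite matching on mask overlap (intersection-over-union,
#' descending; ties broken by smaller centroid distance), accepting matches
#' with IoU at or above `iou_min`. An unmatched mother mapping onto two
#' unmatched masks whose union overlaps her at `iou_min` or more is recorded
#' as a division. Unmatched new masks start parentless tracks; unmatched old
#' masks may be re-found across a single missing frame (gap closing), after
#' which they terminate.
#'
#' @param labels integer label array (`height x width x n_frames`), frames
#'   0-based downstream.
#' @param cells optional observation table from [measureStack()] to carry
#'   geometry into the output.
#' @param frame_interval hours per frame (for ages).
#' @param iou_min acceptance threshold.
#' @param gap_close allow re-finding a track after one missing frame.
#' @return list with `tracks` (data.frame: `track_id`, `frame`, `cell_id`,
#'   `age_h`, plus geometry columns when `cells` is given) and `lineage`
#'   (data.frame: `track_id`, `parent`, `birth_frame` (`NA` when present at
#'   start), `division_frame` (`NA` when none)).
#' @export
trackCells <- function(labels, cells = NULL, frame_interval = 0.5,
                       iou_min = 0.3, gap_close = TRUE) {
  stopifnot(length(dim(labels)) == 3L)
  nF <- dim(labels)[3]
  if (nF < 2L) stop("need at least 2 frames of labels to track")

  trackOf <- list()  # per frame: named map label -> track id
  nextTrack <- 1L
  lineage <- data.frame(track_id = integer(0), parent = integer(0),
                        birth_frame = integer(0), division_frame = integer(0))
  newTrack <- function(parent, birth) {
    id <- nextTrack; nextTrack <<- nextTrack + 1L
    lineage <<- rbind(lineage, data.frame(
      track_id = id, parent = parent, birth_frame = birth,
      division_frame = NA_integer_))
    id
  }

  lab1 <- labels[, , 1L]
  ids1 <- sort(unique(lab1[lab1 > 0L]))
  trackOf[[1L]] <- stats::setNames(
    vapply(ids1, function(i) newTrack(NA_integer_, NA_integer_), integer(1)),
    ids1)
  pending <- NULL  # masks unmatched at the previous transition

  for (f in 2:nF) {
    la <- labels[, , f - 1L]
    lb <- labels[, , f]
    m <- .matchFrames(la, lb, iou_min = iou_min)
    idsB <- sort(unique(lb[lb > 0L]))
    mapB <- stats::setNames(rep(NA_integer_, length(idsB)), idsB)
    matchedB <- integer(0)

    if (!is.null(m$cont)) for (k in seq_len(nrow(m$cont))) {
      mapB[as.character(m$cont$b[k])] <-
        trackOf[[f - 1L]][[as.character(m$cont$a[k])]]
      matchedB <- c(matchedB, m$cont$b[k])
    }
    if (!is.null(m$divs)) for (k in seq_len(nrow(m$divs))) {
      mother <- trackOf[[f - 1L]][[as.character(m$divs$a[k])]]
      lineage$division_frame[lineage$track_id == mother] <- f - 1L
      for (b in c(m$divs$b1[k], m$divs$b2[k])) {
        mapB[as.character(b)] <- newTrack(mother, f - 1L)
        matchedB <- c(matchedB, b)
      }
    }

    # gap closing across one missing frame
    if (gap_close && !is.null(pending) && length(pending$ids)) {
      ovp <- .overlapTable(pending$lab, lb)
      ovp <- ovp[ovp$a %in% pending$ids & !(ovp$b %in% matchedB), ,
                 drop = FALSE]
      ovp <- ovp[order(-ovp$iou), , drop = FALSE]
      usedP <- integer(0)
      for (k in seq_len(nrow(ovp))) {
        a <- ovp$a[k]; b <- ovp$b[k]
        if (ovp$iou[k] < iou_min) break
        if (a %in% usedP || b %in% matchedB) next
        mapB[as.character(b)] <- pending$tracks[[as.character(a)]]
        usedP <- c(usedP, a); matchedB <- c(matchedB, b)
      }
    }

    # new parentless tracks
    for (b in setdiff(idsB, matchedB))
      mapB[as.character(b)] <- newTrack(NA_integer_, f - 1L)

    pending <- if (gap_close && length(m$lostA)) {
      keep <- la
      keep[!(keep %in% m$lostA)] <- 0L
      list(lab = keep, ids = m$lostA,
           tracks = trackOf[[f - 1L]][as.character(m$lostA)])
    } else NULL
    trackOf[[f]] <- mapB
  }

  rows <- lapply(seq_len(nF), function(f) {
    m <- trackOf[[f]]
    if (length(m) == 0L) return(NULL)
    data.frame(track_id = unname(m), frame = f - 1L,
               cell_id = as.integer(names(m)))
  })
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  birth <- lineage$birth_frame[match(tracks$track_id, lineage$track_id)]
  tracks$age_h <- (tracks$frame - ifelse(is.na(birth), 0L, birth)) *
    frame_interval
  if (!is.null(cells)) {
    key <- paste(tracks$frame, tracks$cell_id)
    ck <- paste(cells$frame, cells$cell_id)
    m <- match(key, ck)
    for (col in c("cx", "cy", "orientation", "axis_length_um", "width_um",
                  "qc_flag"))
      if (col %in% names(cells)) tracks[[col]] <- cells[[col]][m]
  }
  rownames(tracks) <- NULL
  rownames(lineage) <- NULL
  list(tracks = tracks, lineage = lineage)
}

#' Assign generation labels F0 / F1 / F2
#'
#' F0: cells whose birth was not observed (present at acquisition start) but
#' whose division was. F1: cells born from the division of an F0 cell that
#' divided later. F2: daughters of F1 cells that never divided and were still
#' present in the final frame. Everything else is `unassigned`.
#'
#' @param lineage lineage table from [trackCells()].
#' @param tracks tracks table from [trackCells()].
#' @param n_frames total number of frames in the movie.
#' @return the lineage table with an added `generation` column.
#' @export
assignGenerations <- function(lineage, tracks, n_frames) {
  lastFrame <- tapply(tracks$frame, tracks$track_id, max)
  lf <- as.integer(lastFrame[as.character(lineage$track_id)])
  divided <- !is.na(lineage$division_frame)
  gen <- rep("unassigned", nrow(lineage))
  gen[is.na(lineage$birth_frame) & divided] <- "F0"
  pgen <- gen[match(lineage$parent, lineage$track_id)]
  gen[!is.na(lineage$parent) & pgen == "F0" & divided & gen == "unassigned"] <-
    "F1"
  pgen <- gen[match(lineage$parent, lineage$track_id)]
  gen[!is.na(lineage$parent) & pgen == "F1" & !divided &
        lf == n_frames - 1L] <- "F2"
  lineage$generation <- gen
  lineage
}

#' New-pole identity per track and frame
#'
#' The daughter's axis end nearer the division plane (the mother's mid-cell
#' position at division) is the new pole. The identity is then propagated to
#' later frames by matching axis ends to the previous frame's new-pole
#' position. The sign convention matches [quantifyPolarization()]: +1 means
#' the new pole is the axis end with the larger projection (pole B of the
#' thirds partition), -1 the smaller (pole A).
#'
#' @param trackResult list from [trackCells()] (run with `cells` supplied so
#'   geometry is available).
#' @param pixel_size micrometres per pixel.
#' @return data.frame: `track_id`, `frame`, `cell_id`, `new_pole_sign`,
#'   `new_pole_x`, `new_pole_y` (unit vector from the cell centre).
#' @export
poleIdentity <- function(trackResult, pixel_size = 0.1) {
  tracks <- trackResult$tracks
  lineage <- trackResult$lineage
  if (!all(c("cx", "cy", "orientation", "axis_length_um") %in% names(tracks)))
    stop("trackCells() must be run with the cells table to use poleIdentity()")
  out <- list()
  for (tid in lineage$track_id[!is.na(lineage$parent)]) {
    li <- lineage[lineage$track_id == tid, ]
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) == 0L) next
    par <- tracks[tracks$track_id == li$parent &
                    tracks$frame == li$birth_frame - 1L, , drop = FALSE]
    if (nrow(par) != 1L || !is.finite(par$cx)) next
    sgn <- NA_integer_
    ref <- c(par$cx, par$cy)   # division plane ~ mother centre at division
    for (i in seq_len(nrow(tr))) {
      if (!is.finite(tr$cx[i])) next
      u <- c(cos(tr$orientation[i]), sin(tr$orientation[i]))
      hl <- tr$axis_length_um[i] / (2 * pixel_size)
      ePlus <- c(tr$cx[i], tr$cy[i]) + u * hl
      eMinus <- c(tr$cx[i], tr$cy[i]) - u * hl
      dPlus <- sum((ePlus - ref)^2); dMinus <- sum((eMinus - ref)^2)
      sgn <- if (dPlus < dMinus) 1L else -1L
      ref <- if (sgn > 0) ePlus else eMinus  # propagate under drift
      out[[length(out) + 1L]] <- data.frame(
        track_id = tid, frame = tr$frame[i], cell_id = tr$cell_id[i],
        new_pole_sign = sgn, new_pole_x = sgn * u[1], new_pole_y = sgn * u[2])
    }
  }
  if (!length(out))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      cell_id = integer(0), new_pole_sign = integer(0),
                      new_pole_x = numeric(0), new_pole_y = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Elongation rate per track
#'
#' Least-squares slope of log(length) against time over the track's
#' lifetime, per hour (the relative, exponential rate); the absolute rate in
#' micrometres per hour is also reported. Tracks with fewer than 3 measured
#' frames get `NA` with a flag.
#'
#' @param tracks tracks table (with `axis_length_um`) from [trackCells()].
#' @param frame_interval hours per frame.
#' @return data.frame: `track_id`, `n_obs`, `rate_per_h`, `rate_um_per_h`,
#'   `flag`.
#' @export
elongationRates <- function(tracks, frame_interval = 0.5) {
  ids <- sort(unique(tracks$track_id))
  rows <- lapply(ids, function(tid) {
    tr <- tracks[tracks$track_id == tid & is.finite(tracks$axis_length_um) &
                   tracks$axis_length_um > 0, , drop = FALSE]
    n <- nrow(tr)
    if (n < 3L)
      return(data.frame(track_id = tid, n_obs = n, rate_per_h = NA_real_,
                        rate_um_per_h = NA_real_, flag = "too_short"))
    tt <- tr$frame * frame_interval
    r <- stats::coef(stats::lm(log(tr$axis_length_um) ~ tt))[2]
    ra <- stats::coef(stats::lm(tr$axis_length_um ~ tt))[2]
    data.frame(track_id = tid, n_obs = n, rate_per_h = unname(r),
               rate_um_per_h = unname(ra), flag = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean cell age at a frame, and the whole age curve
#'
#' Arithmetic mean of cell ages; cells present from acquisition start are
#' aged from frame 0 (ages of the initial inoculum count from acquisition start).
#'
#' @param tracks tracks table from [trackCells()].
#' @param frame 0-based frame index.
#' @return `meanAge`: hours (NA with a warning when no cells).
#' @export
meanAge <- function(tracks, frame) {
  ages <- tracks$age_h[tracks$frame == frame]
  if ("qc_flag" %in% names(tracks))
    ages <- tracks$age_h[tracks$frame == frame &
                           (is.na(tracks$qc_flag) | tracks$qc_flag == "ok")]
  if (length(ages) == 0L) {
    warning("no cells at frame ", frame, "; mean age undefined")
    return(NA_real_)
  }
  mean(ages)
}

#' @rdname meanAge
#' @return `meanAgeCurve`: data.frame `frame`, `time_h`, `n`, `mean_age_h`.
#' @param frame_interval hours per frame.
#' @export
meanAgeCurve <- function(tracks, frame_interval = 0.5) {
  frames <- sort(unique(tracks$frame))
  data.frame(frame = frames, time_h = frames * frame_interval,
             n = vapply(frames, function(f) sum(tracks$frame == f),
                        integer(1)),
             mean_age_h = vapply(frames, function(f)
               suppressWarnings(meanAge(tracks, f)), numeric(1)))
}
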