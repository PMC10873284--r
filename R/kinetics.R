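# Lag-time and depolarization-time analyses: growth resumption kinetics.

#' Lag time (time to first division) per track
#'
#' For every track present from acquisition start: the first division frame
#' times the frame interval. Tracks that never divide are censored at the
#' observation horizon. Tracks appearing later are excluded with a flag.
#'
#' @param trackResult list from [trackCells()].
#' @param frame_interval hours per frame.
#' @param n_frames number of frames (the observation horizon).
#' @param condition optional condition label stored with each record.
#' @return data.frame: `track_id`, `condition`, `lag_h` (`NA` when
#'   censored), `censored`, `horizon_h`.
#' @export
lagTimes <- function(trackResult, frame_interval = 0.5, n_frames = NULL,
                     condition = NA_character_) {
  lineage <- trackResult$lineage
  tracks <- trackResult$tracks
  if (is.null(n_frames)) n_frames <- max(tracks$frame) + 1L
  horizon <- n_frames * frame_interval
  first <- tapply(tracks$frame, tracks$track_id, min)
  atStart <- lineage$track_id[is.na(lineage$birth_frame) &
                                first[as.character(lineage$track_id)] == 0L]
  if (length(atStart) == 0L)
    return(data.frame(track_id = integer(0), condition = character(0),
                      lag_h = numeric(0), censored = logical(0),
                      horizon_h = numeric(0)))
  rows <- lapply(atStart, function(tid) {
    df <- lineage$division_frame[lineage$track_id == tid]
    if (is.na(df))
      data.frame(track_id = tid, condition = condition, lag_h = NA_real_,
                 censored = TRUE, horizon_h = horizon)
    else
      data.frame(track_id = tid, condition = condition,
                 lag_h = df * frame_interval, censored = FALSE,
                 horizon_h = horizon)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Depolarization time per initially polarized track
#'
#' For every track classified polarized at frame 0: the first frame from
#' which the classifier label stays "homogeneous" for at least `k`
#' consecutive frames (a persistence rule against classifier flicker), times
#' the frame interval. `NA` when the cell never sustainedly depolarizes, or
#' (with flag `not_polarized_at_start`) when the track did not start
#' polarized.
#'
#' @param records polarization table from [quantifyPolarization()].
#' @param trackResult list from [trackCells()].
#' @param frame_interval hours per frame.
#' @param k persistence (consecutive homogeneous frames) required.
#' @return data.frame: `track_id`, `depol_h`, `flag`.
#' @export
depolarizationTimes <- function(records, trackResult, frame_interval = 0.5,
                                k = 2L) {
  tracks <- trackResult$tracks
  key <- paste(records$frame, records$cell_id)
  ids <- sort(unique(tracks$track_id[tracks$frame == 0L]))
  rows <- lapply(ids, function(tid) {
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    lab <- records$label[match(paste(tr$frame, tr$cell_id), key)]
    known <- which(!is.na(lab))
    if (!length(known) || tr$frame[known[1]] != 0L ||
        lab[known[1]] != "polarized")
      return(data.frame(track_id = tid, depol_h = NA_real_,
                        flag = "not_polarized_at_start"))
    homo <- !is.na(lab) & lab == "homogeneous"
    run <- rle(homo)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    hit <- which(run$values & run$lengths >= k)
    if (!length(hit))
      return(data.frame(track_id = tid, depol_h = NA_real_,
                        flag = "never_depolarized"))
    data.frame(track_id = tid,
               depol_h = tr$frame[starts[hit[1]]] * frame_interval,
               flag = "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare lag-time distributions between conditions
#'
#' Per condition: n, median, 25th/75th percentiles (linear-interpolation
#' quantiles, R type 7) and censoring counts; pairwise two-sided
#' Wilcoxon rank-sum tests on the uncensored lag times. Censored records are
#' reported but excluded from the tests.
#'
#' @param lagRecords row-bound output of [lagTimes()] with a `condition`
#'   column.
#' @param min_uncensored minimum uncensored records per group for testing.
#' @return list with `summary` (per-condition table) and `tests` (pairwise
#'   rank-sum results; NULL when no test could be run).
#' @export
compareConditions <- function(lagRecords, min_uncensored = 5L) {
  conds <- unique(lagRecords$condition)
  if (length(conds) < 2L) stop("need at least two conditions")
  summ <- do.call(rbind, lapply(conds, function(cc) {
    g <- lagRecords[lagRecords$condition == cc, ]
    unc <- g$lag_h[!g$censored]
    data.frame(condition = cc, n = nrow(g), n_censored = sum(g$censored),
               n_uncensored = length(unc),
               median_h = if (length(unc)) stats::median(unc) else NA_real_,
               q25_h = if (length(unc))
                 unname(stats::quantile(unc, 0.25, type = 7)) else NA_real_,
               q75_h = if (length(unc))
                 unname(stats::quantile(unc, 0.75, type = 7)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  tests <- list()
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (j <= i) next
    gi <- lagRecords[lagRecords$condition == conds[i] & !lagRecords$censored, ]
    gj <- lagRecords[lagRecords$condition == conds[j] & !lagRecords$censored, ]
    if (nrow(gi) < min_uncensored || nrow(gj) < min_uncensored) {
      warning("skipping test ", conds[i], " vs ", conds[j],
              ": too few uncensored records")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(gi$lag_h, gj$lag_h,
                                              alternative = "two.sided"))
    tests[[length(tests) + 1L]] <- data.frame(
      condition_1 = conds[i], condition_2 = conds[j],
      n_1 = nrow(gi), n_2 = nrow(gj),
      median_diff_h = stats::median(gi$lag_h) - stats::median(gj$lag_h),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      stringsAsFactors = FALSE)
  }
  list(summary = summ,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}
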