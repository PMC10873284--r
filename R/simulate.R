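#' Build a simulation configuration
#'
#' Constructor for [SimulationConfig-class] with defaults chosen to emulate a
#' rod-shaped *Pseudomonas*-like cell growing on an agarose pad imaged every
#' 30 minutes for 18 h: founders acclimate (lag), the microcolony grows
#' exponentially, arrests at carrying capacity (stationary phase), and
#' arrested cells then relocate a fraction of their periplasmic fluorophore
#' into a polar focus, biased towards the new pole. Optional events impose
#' division arrest at a given frame (a chemical stressor) or release the
#' colony to fresh medium, after which polarized cells first depolarize and
#' only then resume elongation.
#'
#' @param seed master seed (integer).
#' @param ... any [SimulationConfig-class] field, using the slot names
#'   (e.g. `n_frames`, `carrying_capacity`, `new_pole_bias`).
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 1, n_frames = 10L, carrying_capacity = 20L)
#' cfg
#' @export
simulationConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    frame_interval = 0.5,
    n_frames = 36L,
    pixel_size = 0.1,
    cell_width = 0.8,
    birth_length = 2.0,
    division_length = 4.0,
    elongation_rate = 0.28,
    lag_duration_mean = 1.5,
    lag_duration_sd = 0.5,
    carrying_capacity = 100L,
    arrest_frame = NA_integer_,
    polarization_onset_mean = 3.0,
    polarization_onset_sd = 1.5,
    new_pole_bias = 0.8,
    depolarization_delay_mean = 2.0,
    depolarization_delay_sd = 0.75,
    release_frame = NA_integer_,
    initial_polarized = 0.0,
    periplasm_intensity = 2000,
    focus_fraction = 0.5,
    focus_sigma = 0.15,
    psf_sigma = 0.1,
    read_noise_sd = 2.0,
    shot_noise = TRUE,
    producer = TRUE,
    crossfeed = FALSE,
    crossfeed_factor = 1.0,
    reporter = FALSE,
    reporter_intensity = 1000,
    n_initial = 4L,
    placement = "clustered",
    phase_intensity = 500,
    img_margin = 3.0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  intSlots <- c("seed", "n_frames", "carrying_capacity", "arrest_frame",
                "release_frame", "n_initial")
  for (s in intSlots) defaults[[s]] <- as.integer(defaults[[s]])
  for (s in setdiff(names(defaults), c(intSlots, "shot_noise", "producer",
                                       "crossfeed", "reporter", "placement")))
    defaults[[s]] <- as.numeric(defaults[[s]])
  defaults$placement <- match.arg(defaults$placement,
                                  c("clustered", "grid"))
  do.call(new, c(list(Class = "SimulationConfig"), defaults))
}

#' Named scenario presets
#'
#' Convenience constructors for the study conditions exercised throughout the
#' package: `"growth"` (lag, exponential growth, arrest at carrying
#' capacity), `"arrest"` (division arrest imposed at frame 0, as under an
#' iron chelator or translation inhibitor), `"release"` (cells start
#' polarized and division-arrested, are released to fresh medium at frame 0,
#' depolarize and then regrow), and `"colocalization"` (growth scenario with
#' a second periplasmic reporter channel sharing the pyoverdin distribution).
#'
#' @param name scenario name.
#' @param seed master seed.
#' @param ... field overrides passed on to [simulationConfig()].
#' @return a [SimulationConfig-class].
#' @export
scenarioConfig <- function(name = c("growth", "arrest", "release",
                                    "colocalization"),
                           seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    growth = list(),
    arrest = list(arrest_frame = 0L, n_initial = 30L, n_frames = 20L),
    release = list(initial_polarized = 1.0, release_frame = 0L,
                   n_initial = 30L, n_frames = 36L),
    colocalization = list(reporter = TRUE)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(simulationConfig, c(list(seed = seed), base))
}

# Pairwise hard-body overlap relaxation: cells are pushed apart along their
# centre-to-centre vectors until axis-sample points are ~one cell width apart.
relaxOverlaps <- function(st, width, iters = 40L, npts = 7L) {
  n <- nrow(st)
  if (n < 2L) return(st)
  minsep <- width * 0.95
  fr <- seq(-1, 1, length.out = npts)
  for (it in seq_len(iters)) {
    half <- pmax(st$len / 2 - width / 2, 1e-6)
    ux <- cos(st$theta); uy <- sin(st$theta)
    # candidate pairs by bounding-circle overlap
    reach <- st$len / 2 + width
    dx <- outer(st$cx, st$cx, "-"); dy <- outer(st$cy, st$cy, "-")
    dd <- sqrt(dx^2 + dy^2)
    lim <- outer(reach, reach, "+")
    cand <- which(upper.tri(dd) & dd < lim, arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    i <- cand[, 1]; j <- cand[, 2]
    # min distance over axis sample points
    pxi <- st$cx[i] + outer(half[i] * ux[i], fr)   # k x npts
    pyi <- st$cy[i] + outer(half[i] * uy[i], fr)
    pxj <- st$cx[j] + outer(half[j] * ux[j], fr)
    pyj <- st$cy[j] + outer(half[j] * uy[j], fr)
    dmin <- rep(Inf, length(i))
    for (a in seq_len(npts)) for (b in seq_len(npts)) {
      dab <- sqrt((pxi[, a] - pxj[, b])^2 + (pyi[, a] - pyj[, b])^2)
      dmin <- pmin(dmin, dab)
    }
    ov <- minsep - dmin
    hit <- which(ov > 1e-9)
    if (length(hit) == 0L) break
    # accumulate displacements
    mx <- numeric(n); my <- numeric(n)
    for (k in hit) {
      a <- i[k]; b <- j[k]
      vx <- st$cx[a] - st$cx[b]; vy <- st$cy[a] - st$cy[b]
      vn <- sqrt(vx^2 + vy^2)
      if (vn < 1e-9) { vx <- cos(a); vy <- sin(a); vn <- 1 }
      push <- ov[k] / 2
      mx[a] <- mx[a] + push * vx / vn; my[a] <- my[a] + push * vy / vn
      mx[b] <- mx[b] - push * vx / vn; my[b] <- my[b] - push * vy / vn
    }
    st$cx <- st$cx + mx; st$cy <- st$cy + my
  }
  st
}

#' Simulate a microcolony with full ground truth
#'
#' Agent-based forward model: founder cells placed on a pad acclimate for a
#' sampled lag, elongate exponentially in length, divide symmetrically (with
#' a +/- 5 % stochastic asymmetry) at the division length, and stop dividing
#' when the colony reaches carrying capacity or when an arrest frame is
#' imposed. Each arrested cell forms a polar fluorophore focus after a
#' sampled onset delay, at the new pole with probability `new_pole_bias`.
#' After an optional release event, each polarized cell depolarizes after a
#' sampled delay and only then resumes elongation. Overlapping cells are
#' relaxed by hard-body repulsion along centre-to-centre vectors. All draws
#' come from per-cell sub-streams of the master seed, so the result is
#' deterministic and independent of processing order.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SimTruth-class].
#' @examples
#' truth <- simulateColony(simulationConfig(seed = 7, n_frames = 12L,
#'                                          carrying_capacity = 16L))
#' truth
#' @export
simulateColony <- function(config) {
  validObject(config)
  cfg <- config
  dt <- cfg@frame_interval
  nF <- cfg@n_frames
  hardLimit <- 4L * cfg@carrying_capacity

  # founders
  n0 <- cfg@n_initial
  st <- data.frame(
    id = seq_len(n0), parent = NA_integer_, birth_frame = NA_integer_,
    cx = 0, cy = 0, theta = 0, len = 0, np_sign = 1L,
    lag_end = 0, onset_t = Inf, depol_t = Inf, resume_t = Inf,
    arrested = FALSE, polarized = FALSE, focus_pole = "none",
    stringsAsFactors = FALSE
  )
  spread <- max(2.5, sqrt(n0) * 2.2)
  ncolGrid <- ceiling(sqrt(n0))
  gridStep <- cfg@division_length * 1.6
  for (k in seq_len(n0)) {
    dr <- cellDraws(cfg@seed, k)
    if (cfg@placement == "grid") {
      # sparse regular field of isolated cells (calibration scenarios)
      st$cx[k] <- ((k - 1L) %% ncolGrid) * gridStep +
        (dr$place[1] - 0.5) * 0.5
      st$cy[k] <- ((k - 1L) %/% ncolGrid) * gridStep +
        (dr$place[2] - 0.5) * 0.5
    } else {
      ang <- dr$place[1] * 2 * pi
      rad <- sqrt(dr$place[2]) * spread
      st$cx[k] <- rad * cos(ang)
      st$cy[k] <- rad * sin(ang)
    }
    st$theta[k] <- dr$place[3] * pi
    st$len[k] <- cfg@birth_length +
      dr$place[4] * (cfg@division_length - cfg@birth_length) * 0.85
    st$np_sign[k] <- if (dr$np_u < 0.5) 1L else -1L
    st$lag_end[k] <- max(0, cfg@lag_duration_mean + cfg@lag_duration_sd * dr$lag)
    if (cfg@initial_polarized > 0 && dr$init_pol < cfg@initial_polarized) {
      st$polarized[k] <- TRUE
      st$arrested[k] <- TRUE
      st$lag_end[k] <- Inf
      st$focus_pole[k] <- if (dr$pole_u < cfg@new_pole_bias) "new" else "old"
    }
  }
  st <- relaxOverlaps(st, cfg@cell_width, iters = 30L)

  lineage <- data.frame(id = st$id, parent = NA_integer_,
                        birth_frame = NA_integer_,
                        division_frame = NA_integer_)
  nextId <- n0 + 1L
  colonyArrested <- any(st$arrested) && all(st$arrested)
  arrestKind <- if (colonyArrested) "arrested" else NA_character_
  released <- FALSE
  releaseFired <- FALSE
  releaseT <- NA_real_
  rows <- vector("list", nF)

  for (f in 0L:(nF - 1L)) {
    t <- f * dt
    tPrev <- t - dt

    if (f > 0L) {
      # --- advance by one interval: growth, then divisions -----------------
      grows <- if (released) {
        st$resume_t <= tPrev + 1e-9
      } else {
        !st$arrested & !colonyArrested & st$lag_end <= tPrev + 1e-9
      }
      st$len[grows] <- st$len[grows] * exp(cfg@elongation_rate * dt)

      divide <- grows & st$len >= cfg@division_length & !colonyArrested
      if (any(divide)) {
        newRows <- list()
        for (k in which(divide)) {
          m <- st[k, ]
          um <- c(cos(m$theta), sin(m$theta))
          drm <- cellDraws(cfg@seed, m$id)
          frac <- drm$div_frac
          idA <- nextId; idB <- nextId + 1L; nextId <- nextId + 2L
          mk <- function(id, lenD, cD, npDir) {
            dr <- cellDraws(cfg@seed, id)
            th <- (m$theta + dr$jitter) %% pi
            u <- c(cos(th), sin(th))
            sgn <- if (sum(npDir * u) >= 0) 1L else -1L
            data.frame(id = id, parent = m$id, birth_frame = f,
                       cx = cD[1], cy = cD[2], theta = th, len = lenD,
                       np_sign = sgn, lag_end = 0, onset_t = Inf,
                       depol_t = Inf, resume_t = -Inf,
                       arrested = FALSE, polarized = FALSE,
                       focus_pole = "none", stringsAsFactors = FALSE)
          }
          # mother spans [-Lm/2, Lm/2] along um; A takes the -um side
          lenA <- frac * m$len; lenB <- (1 - frac) * m$len
          cA <- c(m$cx, m$cy) + um * (-m$len / 2 + lenA / 2)
          cB <- c(m$cx, m$cy) + um * (m$len / 2 - lenB / 2)
          newRows[[length(newRows) + 1L]] <- mk(idA, lenA, cA, +um)
          newRows[[length(newRows) + 1L]] <- mk(idB, lenB, cB, -um)
          lineage$division_frame[lineage$id == m$id] <- f
          lineage <- rbind(lineage,
            data.frame(id = c(idA, idB), parent = m$id, birth_frame = f,
                       division_frame = NA_integer_))
        }
        st <- rbind(st[!divide, , drop = FALSE], do.call(rbind, newRows))
      }
      if (nrow(st) > hardLimit)
        stop("runaway growth: cell count ", nrow(st),
             " exceeded the hard limit of ", hardLimit)
    }

    # --- global events at time t -----------------------------------------
    if (!releaseFired && !is.na(cfg@release_frame) &&
        f >= cfg@release_frame) {
      released <- TRUE
      releaseFired <- TRUE
      releaseT <- t
      pol <- st$polarized
      for (k in which(pol)) {
        dr <- cellDraws(cfg@seed, st$id[k])
        delay <- max(0, cfg@depolarization_delay_mean +
                          cfg@depolarization_delay_sd * dr$depol)
        st$depol_t[k] <- releaseT + delay
        st$resume_t[k] <- st$depol_t[k]
      }
      st$resume_t[!pol] <- releaseT
      st$arrested <- FALSE
      colonyArrested <- FALSE
    }
    if (!colonyArrested &&
        (nrow(st) >= cfg@carrying_capacity ||
           (!released && !is.na(cfg@arrest_frame) &&
              f >= cfg@arrest_frame))) {
      # a released colony that regrows to carrying capacity re-enters
      # stationary phase (and its cells repolarize after the onset delay)
      if (released && nrow(st) >= cfg@carrying_capacity) {
        released <- FALSE
        st$onset_t <- Inf
      }
      colonyArrested <- TRUE
      arrestKind <- if (!released && !is.na(cfg@arrest_frame) &&
                          f >= cfg@arrest_frame &&
                          nrow(st) < cfg@carrying_capacity)
        "arrested" else "stationary"
      for (k in seq_len(nrow(st))) {
        if (is.infinite(st$onset_t[k])) {
          dr <- cellDraws(cfg@seed, st$id[k])
          st$onset_t[k] <- t + max(0, cfg@polarization_onset_mean +
                                        cfg@polarization_onset_sd * dr$onset)
        }
      }
      st$arrested <- TRUE
    }

    # --- per-cell state updates ------------------------------------------
    onset <- st$arrested & !st$polarized & t >= st$onset_t - 1e-9
    for (k in which(onset)) {
      dr <- cellDraws(cfg@seed, st$id[k])
      st$polarized[k] <- TRUE
      st$focus_pole[k] <- if (dr$pole_u < cfg@new_pole_bias) "new" else "old"
    }
    if (released) {
      depol <- st$polarized & t >= st$depol_t - 1e-9
      st$polarized[depol] <- FALSE
      st$focus_pole[depol] <- "none"
    }

    if (f > 0L) st <- relaxOverlaps(st, cfg@cell_width)

    # --- record frame ------------------------------------------------------
    phase <- rep("exponential", nrow(st))
    if (released) {
      phase[] <- "released"
    } else if (colonyArrested) {
      phase[] <- arrestKind
    } else {
      inLag <- st$lag_end > t + 1e-9 & is.na(st$parent)
      phase[inLag] <- "lag"
      phase[st$arrested] <- "arrested"   # individually arrested founders
    }
    if (cfg@producer) {
      tot <- cfg@periplasm_intensity * st$len
    } else if (cfg@crossfeed) {
      tot <- rep(cfg@crossfeed_factor * cfg@periplasm_intensity * mean(st$len),
                 nrow(st))
    } else {
      tot <- rep(0, nrow(st))
    }
    ux <- cos(st$theta); uy <- sin(st$theta)
    rows[[f + 1L]] <- data.frame(
      frame = f, id = st$id, parent = st$parent,
      birth_frame = st$birth_frame,
      cx = st$cx, cy = st$cy, theta = st$theta, length_um = st$len,
      width_um = cfg@cell_width, phase = phase, polarized = st$polarized,
      focus_pole = st$focus_pole,
      new_pole_x = st$np_sign * ux, new_pole_y = st$np_sign * uy,
      total_fluorophore = tot, stringsAsFactors = FALSE
    )
  }

  cells <- do.call(rbind, rows)
  # convert um world coordinates to a fixed pixel canvas
  reach <- cells$length_um / 2 + cfg@cell_width / 2
  xmin <- min(cells$cx - reach); xmax <- max(cells$cx + reach)
  ymin <- min(cells$cy - reach); ymax <- max(cells$cy + reach)
  m <- cfg@img_margin
  W <- as.integer(ceiling((xmax - xmin + 2 * m) / cfg@pixel_size))
  H <- as.integer(ceiling((ymax - ymin + 2 * m) / cfg@pixel_size))
  cells$cx <- (cells$cx - xmin + m) / cfg@pixel_size
  cells$cy <- (cells$cy - ymin + m) / cfg@pixel_size
  rownames(cells) <- NULL
  rownames(lineage) <- NULL
  new("SimTruth", cells = cells, lineage = lineage, config = cfg,
      dims = c(H, W))
}
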