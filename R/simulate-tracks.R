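# Seeded generators of synthetic single-particle tracks with known ground
# truth: a two-state (free / transiently trapped) diffusion simulator used to
# benchmark the confinement detector, and a dwell-time simulator that couples
# membrane unbinding with per-frame photobleaching.

# Nearest-trap-zone lookup. Returns list(inZone, cx, cy, id) vectorized over
# positions.
nearestZone <- function(x, y, zones) {
  if (is.list(zones) && !is.data.frame(zones) &&
      identical(zones$type, "grid")) {
    sp <- zones$spacing
    r <- zones$radius
    ix <- round((x - sp / 2) / sp)
    iy <- round((y - sp / 2) / sp)
    cx <- sp / 2 + ix * sp
    cy <- sp / 2 + iy * sp
    inZone <- (x - cx)^2 + (y - cy)^2 <= r^2
    list(inZone = inZone, cx = cx, cy = cy, r = rep(r, length(x)),
         id = paste0("g", ix, "_", iy))
  } else if (is.data.frame(zones)) {
    n <- length(x)
    inZone <- logical(n); cx <- cy <- rr <- numeric(n); id <- character(n)
    for (i in seq_len(n)) {
      d2 <- (zones$x - x[i])^2 + (zones$y - y[i])^2
      j <- which.min(d2)
      inZone[i] <- length(j) > 0 && d2[j] <= zones$radius[j]^2
      if (length(j)) {
        cx[i] <- zones$x[j]; cy[i] <- zones$y[j]; rr[i] <- zones$radius[j]
        id[i] <- as.character(j)
      }
    }
    list(inZone = inZone, cx = cx, cy = cy, r = rr, id = id)
  } else {
    stop("trapZones must be a data.frame(x, y, radius) or a grid spec")
  }
}

# Fold positions into [0, L] (reflecting boundaries).
reflectInto <- function(p, L) {
  p <- p %% (2 * L)
  ifelse(p > L, 2 * L - p, p)
}

#' Simulate two-state (free / transiently trapped) single-molecule tracks
#'
#' Molecules perform Brownian motion with per-axis displacement sd
#' sqrt(2 D dt), where D switches between the free and the trapped
#' coefficient. A free molecule that finds itself over a trap zone binds
#' with per-frame probability 1 - exp(-kBind dt); a trapped molecule
#' diffuses with the trapped coefficient tethered to the zone (reflected at
#' the zone boundary) and unbinds with per-frame probability
#' 1 - exp(-kUnbind dt). State transitions are evaluated once per frame;
#' sub-frame switching is not modelled, matching the frame-based resolution
#' of the downstream detector. Observed positions carry Gaussian
#' localization noise; ground-truth trapping intervals are recorded from the
#' true states.
#'
#' @param config A [TwoStateSimConfig-class] (see [twoStateSimConfig()]).
#' @return A list with elements
#'   \describe{
#'     \item{tracks}{[TrackSet-class] of observed (noisy) positions.}
#'     \item{truth}{data.frame of ground-truth events: `track_id`,
#'       `start_time`, `end_time`, `duration` (s), `zone_id`, and `censored`
#'       (TRUE when the molecule was still trapped at the last frame).}
#'   }
#' @examples
#' sim <- simulateTwoStateTracks(twoStateSimConfig(nMolecules = 5,
#'                                                 nFrames = 100, seed = 7))
#' nTracks(sim$tracks)
#' head(sim$truth)
#' @export
simulateTwoStateTracks <- function(config) {
  stopifnot(is(config, "TwoStateSimConfig"))
  validObject(config)
  n <- config@nMolecules
  tFrames <- config@nFrames
  dt <- config@frameInterval
  L <- config@fovSize
  sdFree <- sqrt(2 * config@dFree * dt)
  sdTrap <- sqrt(2 * config@dTrapped * dt)
  pBind <- 1 - exp(-config@kBind * dt)
  pUnbind <- 1 - exp(-config@kUnbind * dt)

  withSeed(config@seed, {
    x <- matrix(NA_real_, n, tFrames)
    y <- matrix(NA_real_, n, tFrames)
    x[, 1] <- runif(n, 0, L)
    y[, 1] <- runif(n, 0, L)
    trapped <- logical(n)
    zx <- zy <- zr <- rep(NA_real_, n)
    zid <- rep(NA_character_, n)
    evStart <- rep(NA_integer_, n)
    events <- vector("list", 0)

    recordTransitions <- function(frame) {
      # frame is 0-based; called after arrival at `frame`
      if (any(trapped)) {
        un <- trapped & (runif(n) < pUnbind)
        for (i in which(un)) {
          events[[length(events) + 1]] <<- data.frame(
            mol = i, start_frame = evStart[i], end_frame = frame,
            zone_id = zid[i], censored = FALSE)
        }
        trapped[un] <<- FALSE
        evStart[un] <<- NA_integer_
      }
      freeIdx <- which(!trapped)
      if (length(freeIdx) && pBind > 0) {
        nz <- nearestZone(x[freeIdx, frame + 1L], y[freeIdx, frame + 1L],
                          config@trapZones)
        binds <- nz$inZone & (runif(length(freeIdx)) < pBind)
        if (any(binds)) {
          cand <- freeIdx[binds]
          trapped[cand] <<- TRUE
          zx[cand] <<- nz$cx[binds]; zy[cand] <<- nz$cy[binds]
          zr[cand] <<- nz$r[binds]; zid[cand] <<- nz$id[binds]
          evStart[cand] <<- frame
        }
      }
    }

    recordTransitions(0L)
    for (f in seq_len(tFrames - 1L)) {
      prevX <- x[, f]; prevY <- y[, f]
      stepSd <- ifelse(trapped, sdTrap, sdFree)
      nx <- prevX + rnorm(n, 0, stepSd)
      ny <- prevY + rnorm(n, 0, stepSd)
      # tether trapped molecules: radial reflection at the zone boundary
      if (any(trapped)) {
        ti <- which(trapped)
        dx <- nx[ti] - zx[ti]; dy <- ny[ti] - zy[ti]
        d <- sqrt(dx^2 + dy^2)
        out <- d > zr[ti]
        if (any(out)) {
          oi <- ti[out]
          dn <- pmax(0, 2 * zr[oi] - d[out])
          sc <- ifelse(d[out] > 0, dn / d[out], 0)
          nx[oi] <- zx[oi] + dx[out] * sc
          ny[oi] <- zy[oi] + dy[out] * sc
        }
      }
      # free molecules reflect at the FOV boundary
      fi <- which(!trapped)
      nx[fi] <- reflectInto(nx[fi], L)
      ny[fi] <- reflectInto(ny[fi], L)
      # crossing probability: reject zone entries with prob 1 - cp
      if (config@crossingProbability < 1 && length(fi)) {
        nzNew <- nearestZone(nx[fi], ny[fi], config@trapZones)
        nzOld <- nearestZone(prevX[fi], prevY[fi], config@trapZones)
        entering <- nzNew$inZone & !nzOld$inZone
        reject <- entering & (runif(length(fi)) > config@crossingProbability)
        nx[fi[reject]] <- prevX[fi[reject]]
        ny[fi[reject]] <- prevY[fi[reject]]
      }
      x[, f + 1L] <- nx
      y[, f + 1L] <- ny
      recordTransitions(f)
    }
    # close censored events
    for (i in which(trapped)) {
      events[[length(events) + 1]] <- data.frame(
        mol = i, start_frame = evStart[i], end_frame = tFrames - 1L,
        zone_id = zid[i], censored = TRUE)
    }

    noise <- config@localizationNoiseSd
    obsX <- x + if (noise > 0) rnorm(n * tFrames, 0, noise) else 0
    obsY <- y + if (noise > 0) rnorm(n * tFrames, 0, noise) else 0

    ids <- sprintf("s%d_m%03d", config@seed, seq_len(n))
    td <- data.frame(
      track_id = rep(ids, each = tFrames),
      frame = rep(seq_len(tFrames) - 1L, times = n),
      t_s = rep((seq_len(tFrames) - 1L) * dt, times = n),
      x_um = as.vector(t(obsX)),
      y_um = as.vector(t(obsY)),
      stringsAsFactors = FALSE)
    truth <- if (length(events)) {
      ev <- do.call(rbind, events)
      data.frame(track_id = ids[ev$mol],
                 start_time = ev$start_frame * dt,
                 end_time = ev$end_frame * dt,
                 duration = (ev$end_frame - ev$start_frame) * dt,
                 zone_id = ev$zone_id,
                 censored = ev$censored,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(track_id = character(0), start_time = numeric(0),
                 end_time = numeric(0), duration = numeric(0),
                 zone_id = character(0), censored = logical(0))
    }
    list(tracks = TrackSet(td, frameInterval = dt), truth = truth)
  })
}

#' Simulate observed membrane dwell times under photobleaching
#'
#' True dwell times are exponential with the configured unbinding rate. At a
#' lapse interval tau_tl with exposure tau_int, a molecule disappears from
#' one frame to the next with probability
#' 1 - exp(-(k_off tau_tl + k_b tau_int)): unbinding acts over the full
#' interval, bleaching only while the shutter is open. The observed dwell is
#' the number of frames the molecule was seen times the lapse interval, so
#' the apparent decay rate at interval tau_tl is
#' k_eff = k_off + k_b tau_int / tau_tl -- the relation exploited by
#' [bleachCorrectedLifetime()].
#'
#' @param config A [DwellSimConfig-class] (see [dwellSimConfig()]).
#' @return Named list of [DwellDataset-class] objects, one per lapse
#'   interval (names are the intervals in seconds).
#' @examples
#' sets <- simulateDwellTracks(dwellSimConfig(nMoleculesPerInterval = 100))
#' vapply(sets, function(d) mean(d@durations), numeric(1))
#' @export
simulateDwellTracks <- function(config) {
  stopifnot(is(config, "DwellSimConfig"))
  validObject(config)
  withSeed(config@seed, {
    out <- lapply(config@lapseIntervals, function(tl) {
      q <- 1 - exp(-(config@kOffTrue * tl +
                     config@bleachRate * config@integrationTime))
      nF <- if (config@nMoleculesPerInterval > 0) {
        rgeom(config@nMoleculesPerInterval, q) + 1L
      } else integer(0)
      DwellDataset(lapseInterval = tl,
                   integrationTime = config@integrationTime,
                   durations = nF * tl)
    })
    names(out) <- as.character(config@lapseIntervals)
    out
  })
}
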