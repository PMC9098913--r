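# S4 containers shared across the analysis modules.

#' Time-lapse image series
#'
#' A single-channel stack of 2D intensity frames with the spatial and
#' temporal calibration needed by every image-level statistic in the
#' package: pixel size in micrometres per pixel and frame interval in
#' seconds.
#'
#' @slot frames numeric array, height x width x T, nonnegative intensities.
#' @slot pixelSize um per pixel, positive scalar.
#' @slot frameInterval seconds between frame starts, positive scalar.
#' @slot channelLabel free-text channel name.
#'
#' @seealso [ImageSeries()] constructor, [loadImageSeries()],
#'   [simulateFilamentMovie()]
#' @export
setClass("ImageSeries",
  representation(
    frames        = "array",
    pixelSize     = "numeric",
    frameInterval = "numeric",
    channelLabel  = "character"
  )
)

setValidity("ImageSeries", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) {
    return("frames must be a 3D array (height x width x T)")
  }
  if (dim(f)[3] < 1L) return("need at least one frame")
  if (anyNA(f) || any(!is.finite(f))) return("frame intensities must be finite")
  if (any(f < 0)) return("frame intensities must be nonnegative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    return("pixelSize must be a positive scalar (um/px)")
  }
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0) {
    return("frameInterval must be a positive scalar (s)")
  }
  TRUE
})

#' Construct an ImageSeries
#'
#' @param frames 3D numeric array (height x width x T) or a list of equally
#'   sized matrices.
#' @param pixelSize um per pixel.
#' @param frameInterval s between frames.
#' @param channelLabel optional channel name.
#' @return An [ImageSeries-class] object.
#' @examples
#' im <- ImageSeries(array(1, dim = c(4, 4, 2)), pixelSize = 0.1,
#'                   frameInterval = 2)
#' nFrames(im)
#' @export
ImageSeries <- function(frames, pixelSize, frameInterval, channelLabel = "") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must have identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  new("ImageSeries", frames = frames, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval),
      channelLabel = as.character(channelLabel))
}

#' @describeIn ImageSeries-class frame stack accessor
#' @param x,object an `ImageSeries`
#' @export
setMethod("frames", "ImageSeries", function(x) x@frames)

#' @describeIn ImageSeries-class pixel size (um/px)
#' @export
setMethod("pixelSize", "ImageSeries", function(x) x@pixelSize)

#' @describeIn ImageSeries-class frame interval (s)
#' @export
setMethod("frameInterval", "ImageSeries", function(x) x@frameInterval)

#' @describeIn ImageSeries-class number of frames
#' @export
setMethod("nFrames", "ImageSeries", function(x) dim(x@frames)[3])

#' @describeIn ImageSeries-class channel label
#' @export
setMethod("channelLabel", "ImageSeries", function(x) x@channelLabel)

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageSeries '%s': %d frame(s) of %d x %d px, %.4g um/px, %.4g s/frame\n",
    object@channelLabel, d[3], d[1], d[2], object@pixelSize,
    object@frameInterval))
  invisible(NULL)
})

#' Set of single-particle tracks
#'
#' Particle trajectories in physical units: one row per localization with
#' track id, integer frame index, time in seconds and x/y position in
#' micrometres. Frame gaps (missed localizations) are preserved; downstream
#' windowed statistics skip windows that span a gap.
#'
#' @slot data data.frame with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, ordered by track then frame.
#' @slot frameInterval acquisition interval in seconds.
#'
#' @seealso [TrackSet()], [readTracks()], [simulateTwoStateTracks()]
#' @export
setClass("TrackSet",
  representation(data = "data.frame", frameInterval = "numeric")
)

setValidity("TrackSet", function(object) {
  d <- object@data
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    return(paste("track data needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(d) > 0) {
    if (anyNA(d[need]) || any(!is.finite(d$x_um)) || any(!is.finite(d$y_um))) {
      return("track coordinates must be finite and non-missing")
    }
    dfr <- unlist(tapply(d$frame, d$track_id, diff, simplify = FALSE),
                  use.names = FALSE)
    if (length(dfr) && any(dfr <= 0)) {
      return("frames must be strictly increasing within each track")
    }
  }
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0) {
    return("frameInterval must be a positive scalar (s)")
  }
  TRUE
})

#' Construct a TrackSet
#'
#' @param data data.frame with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um` (`t_s` is filled in from `frame * frameInterval` when absent).
#' @param frameInterval acquisition interval, s.
#' @return A [TrackSet-class] object.
#' @export
TrackSet <- function(data, frameInterval) {
  if (!"t_s" %in% names(data)) data$t_s <- data$frame * frameInterval
  data <- data[order(data$track_id, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  new("TrackSet", data = data, frameInterval = as.numeric(frameInterval))
}

#' @describeIn TrackSet-class track table accessor
#' @param x,object a `TrackSet`
#' @export
setMethod("trackData", "TrackSet", function(x) x@data)

#' @describeIn TrackSet-class track ids
#' @export
setMethod("trackIds", "TrackSet", function(x) unique(x@data$track_id))

#' @describeIn TrackSet-class number of tracks
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@data$track_id)))

#' @describeIn TrackSet-class frame interval (s)
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s), %d localization(s), %.4g s/frame\n",
              nTracks(object), nrow(object@data), object@frameInterval))
  invisible(NULL)
})

#' Result of a model fit
#'
#' Uniform container for every nonlinear/linear fit in the package: named
#' parameter estimates, their standard errors, a goodness-of-fit summary and
#' a convergence flag. Degenerate fits (unidentifiable parameters, fits at a
#' bound) are returned flagged rather than as silent failures; details live
#' in `diagnostics`.
#'
#' @slot params named numeric parameter estimates.
#' @slot stderr named numeric standard errors (NA when unavailable).
#' @slot rSquared coefficient of determination (NA for ML fits).
#' @slot modelName text identifier of the model.
#' @slot converged logical; FALSE marks flagged fits.
#' @slot diagnostics list of model-specific extras (messages, residuals, ...).
#'
#' @export
setClass("FitResult",
  representation(
    params      = "numeric",
    stderr      = "numeric",
    rSquared    = "numeric",
    modelName   = "character",
    converged   = "logical",
    diagnostics = "list"
  )
)

setValidity("FitResult", function(object) {
  if (is.null(names(object@params)) && length(object@params)) {
    return("params must be named")
  }
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-9) {
    return("rSquared cannot exceed 1")
  }
  TRUE
})

#' Construct a FitResult
#'
#' @param params named numeric vector of estimates.
#' @param stderr named numeric vector of standard errors.
#' @param rSquared goodness of fit (NA if not meaningful).
#' @param modelName model identifier.
#' @param converged logical convergence flag.
#' @param diagnostics list of extras.
#' @return A [FitResult-class] object.
#' @export
FitResult <- function(params, stderr = setNames(rep(NA_real_, length(params)),
                                                names(params)),
                      rSquared = NA_real_, modelName = "",
                      converged = TRUE, diagnostics = list()) {
  new("FitResult", params = params, stderr = stderr,
      rSquared = as.numeric(rSquared), modelName = modelName,
      converged = converged, diagnostics = diagnostics)
}

#' @describeIn FitResult-class parameter estimates
#' @param x,object a `FitResult`
#' @export
setMethod("fitParams", "FitResult", function(x) x@params)

#' @describeIn FitResult-class standard errors
#' @export
setMethod("fitStderr", "FitResult", function(x) x@stderr)

#' @describeIn FitResult-class convergence flag
#' @export
setMethod("isConverged", "FitResult", function(x) x@converged)

#' @describeIn FitResult-class parameter estimates via `coef()`
#' @export
setMethod("coef", "FitResult", function(object) object@params)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]%s\n", object@modelName,
              if (object@converged) "" else " (FLAGGED: not converged)"))
  tab <- data.frame(estimate = object@params,
                    stderr = object@stderr[names(object@params)])
  print(tab)
  if (is.finite(object@rSquared)) {
    cat(sprintf("R-squared: %.4f\n", object@rSquared))
  }
  invisible(NULL)
})

#' Temporal correlation curve
#'
#' Pearson correlation values as a function of time lag, e.g. the temporal
#' autocorrelation of a filament pattern. The lag-0 value of a
#' self-correlation is exactly 1.
#'
#' @slot lags time lags in seconds, strictly increasing.
#' @slot values correlation values in \[-1, 1\].
#'
#' @seealso [temporalAutocorrelation()], [fitExpDecay()]
#' @export
setClass("CorrelationCurve",
  representation(lags = "numeric", values = "numeric"))

setValidity("CorrelationCurve", function(object) {
  if (length(object@lags) != length(object@values)) {
    return("lags and values must have equal length")
  }
  if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
  if (any(abs(object@values) > 1 + 1e-8, na.rm = TRUE)) {
    return("correlation values must lie in [-1, 1]")
  }
  TRUE
})

#' Construct a CorrelationCurve
#'
#' @param lags time lags, s.
#' @param values correlation values in \[-1, 1\].
#' @return A [CorrelationCurve-class] object.
#' @export
CorrelationCurve <- function(lags, values) {
  new("CorrelationCurve", lags = as.numeric(lags), values = as.numeric(values))
}

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags, %.4g..%.4g s\n",
              length(object@lags), min(object@lags), max(object@lags)))
  invisible(NULL)
})

#' Packing-coefficient profile of one track
#'
#' The packing coefficient p quantifies, for a sliding window of n steps,
#' how tightly a trajectory segment folds onto itself: the summed squared
#' step lengths divided by the squared convex-hull area of the segment
#' (units um^-2). Large p marks transient confinement. Windows that span a
#' frame gap carry NA; windows with a degenerate (collinear) hull carry
#' +Inf.
#'
#' @slot trackId id of the source track.
#' @slot times time of each window's first point, s.
#' @slot p packing coefficient per window, um^-2 (NA for gap windows,
#'   +Inf for degenerate hulls).
#' @slot windowN window length in steps.
#' @slot frameInterval acquisition interval, s.
#'
#' @seealso [packingCoefficient()], [detectConfinement()]
#' @export
setClass("PackingProfile",
  representation(trackId = "ANY", times = "numeric", p = "numeric",
                 windowN = "integer", frameInterval = "numeric"))

setValidity("PackingProfile", function(object) {
  if (length(object@times) != length(object@p)) {
    return("times and p must have equal length")
  }
  if (any(object@p < 0, na.rm = TRUE)) {
    return("packing coefficients must be nonnegative")
  }
  TRUE
})

setMethod("show", "PackingProfile", function(object) {
  cat(sprintf(
    "PackingProfile track %s: %d window(s) of n = %d steps (%.3g s frames)\n",
    as.character(object@trackId), length(object@p), object@windowN,
    object@frameInterval))
  invisible(NULL)
})

#' FRAP recovery profile
#'
#' One-dimensional fluorescence profiles around a bleached window, one
#' column per post-bleach time point, normalized to the pre-bleach steady
#' state (so full recovery approaches 1 everywhere). The profile shape over
#' time is what separates recovery by lateral diffusion from recovery by
#' exchange with the solution reservoir.
#'
#' @slot positions positions along the projection axis, um, strictly
#'   increasing; the profile ends are treated as reflecting boundaries.
#' @slot times time since bleach for each column, s.
#' @slot intensities matrix positions x times of normalized fluorescence.
#' @slot bleachWindow c(x0, x1) extent of the bleached region, um.
#' @slot groundTruth list of generator parameters when synthetic (empty for
#'   measured data).
#'
#' @seealso [simulateFrapProfiles()], [extractRecoveryProfile()], [fitFrap()]
#' @export
setClass("RecoveryProfile",
  representation(positions = "numeric", times = "numeric",
                 intensities = "matrix", bleachWindow = "numeric",
                 groundTruth = "list"))

setValidity("RecoveryProfile", function(object) {
  if (any(diff(object@positions) <= 0)) {
    return("positions must be strictly increasing")
  }
  if (!all(dim(object@intensities) ==
           c(length(object@positions), length(object@times)))) {
    return("intensities must be positions x times")
  }
  if (length(object@bleachWindow) != 2L ||
      object@bleachWindow[1] >= object@bleachWindow[2]) {
    return("bleachWindow must be c(x0, x1) with x0 < x1")
  }
  TRUE
})

#' Construct a RecoveryProfile
#'
#' @param positions positions along the profile, um.
#' @param times times since bleach, s.
#' @param intensities matrix positions x times, normalized to pre-bleach.
#' @param bleachWindow c(x0, x1), um.
#' @param groundTruth optional list of true generator parameters.
#' @return A [RecoveryProfile-class] object.
#' @export
RecoveryProfile <- function(positions, times, intensities, bleachWindow,
                            groundTruth = list()) {
  new("RecoveryProfile", positions = as.numeric(positions),
      times = as.numeric(times), intensities = as.matrix(intensities),
      bleachWindow = as.numeric(bleachWindow), groundTruth = groundTruth)
}

setMethod("show", "RecoveryProfile", function(object) {
  cat(sprintf(
    "RecoveryProfile: %d positions x %d times, bleach window [%.3g, %.3g] um\n",
    length(object@positions), length(object@times), object@bleachWindow[1],
    object@bleachWindow[2]))
  invisible(NULL)
})

#' Donor/acceptor intensity trace for acceptor-photobleaching FRET
#'
#' Background levels are per channel and subtracted before efficiency
#' estimation.
#'
#' @slot times frame times, s.
#' @slot donor donor-channel intensities.
#' @slot acceptor acceptor-channel intensities.
#' @slot bleachFrame 1-based index of the first post-bleach frame.
#' @slot background c(donor, acceptor) background levels.
#'
#' @seealso [fretEfficiencyAP()], [simulateFretTrace()]
#' @export
setClass("FretTrace",
  representation(times = "numeric", donor = "numeric", acceptor = "numeric",
                 bleachFrame = "integer", background = "numeric"))

setValidity("FretTrace", function(object) {
  n <- length(object@times)
  if (length(object@donor) != n || length(object@acceptor) != n) {
    return("times, donor and acceptor must have equal length")
  }
  if (object@bleachFrame < 2L || object@bleachFrame > n) {
    return("bleachFrame must lie within the trace (and after frame 1)")
  }
  if (length(object@background) != 2L) {
    return("background must be c(donor, acceptor)")
  }
  TRUE
})

#' Construct a FretTrace
#'
#' @param times frame times, s.
#' @param donor,acceptor channel intensities.
#' @param bleachFrame 1-based index of the first post-bleach frame.
#' @param background c(donor, acceptor) background levels.
#' @return A [FretTrace-class] object.
#' @export
FretTrace <- function(times, donor, acceptor, bleachFrame,
                      background = c(0, 0)) {
  new("FretTrace", times = as.numeric(times), donor = as.numeric(donor),
      acceptor = as.numeric(acceptor), bleachFrame = as.integer(bleachFrame),
      background = as.numeric(background))
}

setMethod("show", "FretTrace", function(object) {
  cat(sprintf("FretTrace: %d frames, bleach at frame %d\n",
              length(object@times), object@bleachFrame))
  invisible(NULL)
})

#' Concentration-response binding series
#'
#' A titration curve from a bulk binding assay (QCM-D frequency shifts or
#' MST normalized fluorescence). Responses keep their native sign; QCM-D
#' frequency shifts are negative on binding.
#'
#' @slot concentrations uM, strictly increasing, nonnegative.
#' @slot responses instrument response at each concentration.
#' @slot responseSd optional per-point standard deviations (length 0 when
#'   absent).
#'
#' @seealso [fitHillQcmd()], [fitHillMst()], [simulateBindingCurve()]
#' @export
setClass("BindingSeries",
  representation(concentrations = "numeric", responses = "numeric",
                 responseSd = "numeric"))

setValidity("BindingSeries", function(object) {
  if (length(object@concentrations) != length(object@responses)) {
    return("concentrations and responses must have equal length")
  }
  if (any(object@concentrations < 0)) {
    return("concentrations must be nonnegative")
  }
  if (any(diff(object@concentrations) <= 0)) {
    return("concentrations must be strictly increasing")
  }
  if (length(object@responseSd) &&
      length(object@responseSd) != length(object@responses)) {
    return("responseSd must match responses in length")
  }
  TRUE
})

#' Construct a BindingSeries
#'
#' @param concentrations uM, strictly increasing.
#' @param responses instrument responses.
#' @param responseSd optional standard deviations.
#' @return A [BindingSeries-class] object.
#' @export
BindingSeries <- function(concentrations, responses, responseSd = numeric(0)) {
  new("BindingSeries", concentrations = as.numeric(concentrations),
      responses = as.numeric(responses), responseSd = as.numeric(responseSd))
}

setMethod("show", "BindingSeries", function(object) {
  cat(sprintf("BindingSeries: %d points, %.4g..%.4g uM\n",
              length(object@concentrations), min(object@concentrations),
              max(object@concentrations)))
  invisible(NULL)
})

#' Dwell-time dataset at one time-lapse interval
#'
#' Observed single-molecule membrane dwell durations at one acquisition
#' interval. Apparent dwell times shorten with photobleaching; combining
#' datasets across several lapse intervals separates the true unbinding rate
#' from bleaching (see [bleachCorrectedLifetime()]).
#'
#' @slot lapseInterval time between frame starts (tau_tl), s.
#' @slot integrationTime exposure time per frame (tau_int), s.
#' @slot durations observed dwell durations, s, positive multiples of the
#'   lapse interval.
#'
#' @export
setClass("DwellDataset",
  representation(lapseInterval = "numeric", integrationTime = "numeric",
                 durations = "numeric"))

setValidity("DwellDataset", function(object) {
  if (object@lapseInterval <= 0) return("lapseInterval must be positive")
  if (object@integrationTime < 0 ||
      object@integrationTime > object@lapseInterval) {
    return("integrationTime must lie in [0, lapseInterval]")
  }
  if (length(object@durations)) {
    if (any(object@durations <= 0)) return("durations must be positive")
    fr <- object@durations / object@lapseInterval
    if (any(abs(fr - round(fr)) > 1e-6)) {
      return("durations must be multiples of the lapse interval")
    }
  }
  TRUE
})

#' Construct a DwellDataset
#'
#' @param lapseInterval tau_tl, s.
#' @param integrationTime tau_int, s.
#' @param durations observed dwell durations, s.
#' @return A [DwellDataset-class] object.
#' @export
DwellDataset <- function(lapseInterval, integrationTime, durations) {
  new("DwellDataset", lapseInterval = as.numeric(lapseInterval),
      integrationTime = as.numeric(integrationTime),
      durations = as.numeric(durations))
}

setMethod("show", "DwellDataset", function(object) {
  cat(sprintf("DwellDataset: tau_tl = %.4g s, %d dwell(s)\n",
              object@lapseInterval, length(object@durations)))
  invisible(NULL)
})

# ---- simulation configs ----

#' Configuration for the two-state (free/trapped) track simulator
#'
#' Molecules diffuse freely with `dFree` and, while over a trap zone, bind
#' with rate `kBind`; bound molecules diffuse with `dTrapped` tethered to
#' the zone (reflected at its boundary) and unbind with rate `kUnbind`.
#'
#' @slot nMolecules molecules per field of view.
#' @slot fovSize side of the square field of view, um.
#' @slot dFree free diffusion coefficient, um^2/s.
#' @slot dTrapped trapped diffusion coefficient, um^2/s (<= dFree).
#' @slot kBind binding rate while over a trap zone, 1/s.
#' @slot kUnbind unbinding rate, 1/s.
#' @slot trapZones either a data.frame(x, y, radius) of disk zones or a list
#'   `list(type = "grid", spacing =, radius =)` describing a regular grid of
#'   disks.
#' @slot crossingProbability probability that a free molecule may enter a
#'   zone, in \[0, 1\].
#' @slot frameInterval s.
#' @slot nFrames frames per track.
#' @slot localizationNoiseSd localization error sd per axis, um.
#' @slot seed integer RNG seed.
#'
#' @seealso [twoStateSimConfig()], [simulateTwoStateTracks()]
#' @export
setClass("TwoStateSimConfig",
  representation(nMolecules = "integer", fovSize = "numeric",
                 dFree = "numeric", dTrapped = "numeric", kBind = "numeric",
                 kUnbind = "numeric", trapZones = "ANY",
                 crossingProbability = "numeric", frameInterval = "numeric",
                 nFrames = "integer", localizationNoiseSd = "numeric",
                 seed = "integer"))

setValidity("TwoStateSimConfig", function(object) {
  chkPos <- function(v, nm, strict = TRUE) {
    if (length(v) != 1L || !is.finite(v) || (if (strict) v <= 0 else v < 0)) {
      sprintf("%s must be a finite %s value", nm,
              if (strict) "positive" else "nonnegative")
    } else NULL
  }
  for (msg in list(chkPos(object@fovSize, "fovSize"),
                   chkPos(object@dFree, "dFree", strict = FALSE),
                   chkPos(object@dTrapped, "dTrapped", strict = FALSE),
                   chkPos(object@kBind, "kBind", strict = FALSE),
                   chkPos(object@kUnbind, "kUnbind", strict = FALSE),
                   chkPos(object@frameInterval, "frameInterval"),
                   chkPos(object@localizationNoiseSd, "localizationNoiseSd",
                          strict = FALSE))) {
    if (!is.null(msg)) return(msg)
  }
  if (object@dTrapped > object@dFree) return("dTrapped must not exceed dFree")
  if (object@crossingProbability < 0 || object@crossingProbability > 1) {
    return("crossingProbability must lie in [0, 1]")
  }
  if (object@nMolecules < 1L) return("nMolecules must be at least 1")
  if (object@nFrames < 2L) return("nFrames must be at least 2")
  TRUE
})

#' Build a TwoStateSimConfig
#'
#' Defaults follow the simulation conditions used to benchmark the
#' confinement detector: 50 molecules per field of view, free diffusion
#' 0.2 um^2/s, trapped diffusion 0.002 um^2/s, crossing probability 1, and
#' trap zones as 25 nm disks on a 0.1 um grid (the zone geometry is a
#' package default; see the methods vignette).
#'
#' @param nMolecules molecules per FOV.
#' @param fovSize um.
#' @param dFree,dTrapped um^2/s.
#' @param kBind,kUnbind 1/s.
#' @param trapZones data.frame(x, y, radius) or
#'   `list(type = "grid", spacing =, radius =)`.
#' @param crossingProbability in \[0, 1\].
#' @param frameInterval s.
#' @param nFrames frames per track.
#' @param localizationNoiseSd um (default 0.02, a typical TIRF single-molecule
#'   localization precision).
#' @param seed integer seed.
#' @return A [TwoStateSimConfig-class] object.
#' @export
twoStateSimConfig <- function(nMolecules = 50, fovSize = 10, dFree = 0.2,
                              dTrapped = 0.002, kBind = 0.3, kUnbind = 1.5,
                              trapZones = list(type = "grid", spacing = 0.1,
                                               radius = 0.025),
                              crossingProbability = 1, frameInterval = 0.051,
                              nFrames = 400, localizationNoiseSd = 0.02,
                              seed = 1L) {
  new("TwoStateSimConfig", nMolecules = as.integer(nMolecules),
      fovSize = as.numeric(fovSize), dFree = as.numeric(dFree),
      dTrapped = as.numeric(dTrapped), kBind = as.numeric(kBind),
      kUnbind = as.numeric(kUnbind), trapZones = trapZones,
      crossingProbability = as.numeric(crossingProbability),
      frameInterval = as.numeric(frameInterval), nFrames = as.integer(nFrames),
      localizationNoiseSd = as.numeric(localizationNoiseSd),
      seed = as.integer(seed))
}

#' Configuration for the dwell-time simulator
#'
#' @slot kOffTrue true unbinding rate, 1/s.
#' @slot bleachRate bleaching rate while the shutter is open, 1/s.
#' @slot integrationTime exposure per frame, s.
#' @slot lapseIntervals acquisition intervals to simulate, s.
#' @slot nMoleculesPerInterval molecules per interval.
#' @slot seed integer RNG seed.
#'
#' @seealso [dwellSimConfig()], [simulateDwellTracks()]
#' @export
setClass("DwellSimConfig",
  representation(kOffTrue = "numeric", bleachRate = "numeric",
                 integrationTime = "numeric", lapseIntervals = "numeric",
                 nMoleculesPerInterval = "integer", seed = "integer"))

setValidity("DwellSimConfig", function(object) {
  if (object@kOffTrue < 0 || object@bleachRate < 0) {
    return("rates must be nonnegative")
  }
  if (length(object@lapseIntervals) == 0L) {
    return("lapseIntervals must not be empty")
  }
  if (any(object@lapseIntervals < object@integrationTime)) {
    return("every lapse interval must be at least the integration time")
  }
  if (object@nMoleculesPerInterval < 0L) {
    return("nMoleculesPerInterval must be nonnegative")
  }
  TRUE
})

#' Build a DwellSimConfig
#'
#' Defaults mirror multi-interval single-molecule residence-time imaging:
#' lapse intervals 0.125-2 s with a 50 ms exposure.
#'
#' @param kOffTrue 1/s.
#' @param bleachRate 1/s during integration.
#' @param integrationTime s.
#' @param lapseIntervals vector of s.
#' @param nMoleculesPerInterval count.
#' @param seed integer seed.
#' @return A [DwellSimConfig-class] object.
#' @export
dwellSimConfig <- function(kOffTrue = 0.05, bleachRate = 4,
                           integrationTime = 0.05,
                           lapseIntervals = c(0.125, 0.25, 0.5, 1, 2),
                           nMoleculesPerInterval = 1000, seed = 1L) {
  new("DwellSimConfig", kOffTrue = as.numeric(kOffTrue),
      bleachRate = as.numeric(bleachRate),
      integrationTime = as.numeric(integrationTime),
      lapseIntervals = as.numeric(lapseIntervals),
      nMoleculesPerInterval = as.integer(nMoleculesPerInterval),
      seed = as.integer(seed))
}

#' Configuration for the dual-colour treadmilling filament movie simulator
#'
#' Channel 1 renders a network of treadmilling filaments (front grows, rear
#' shrinks at `treadmillSpeed`); channel 2 mixes a fraction
#' `channel2Coupling` of the channel-1 line density with a homogeneous
#' background, emulating a second protein that either follows the filament
#' pattern or binds the membrane independently.
#'
#' @slot nFilaments count.
#' @slot treadmillSpeed um/s.
#' @slot filamentLength um.
#' @slot psfSigma Gaussian PSF sigma, um.
#' @slot channel2Coupling fraction in \[0, 1\].
#' @slot noiseGain Poisson photon gain (expected photons per unit density;
#'   0 disables shot noise).
#' @slot readNoiseSd Gaussian read-noise sd in intensity units.
#' @slot pixelSize um/px.
#' @slot frameInterval s.
#' @slot nFrames count (>= 2).
#' @slot fovPixels image side length, px.
#' @slot seed integer RNG seed.
#'
#' @seealso [filamentMovieConfig()], [simulateFilamentMovie()]
#' @export
setClass("FilamentMovieConfig",
  representation(nFilaments = "integer", treadmillSpeed = "numeric",
                 filamentLength = "numeric", psfSigma = "numeric",
                 channel2Coupling = "numeric", noiseGain = "numeric",
                 readNoiseSd = "numeric", pixelSize = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 fovPixels = "integer", seed = "integer"))

setValidity("FilamentMovieConfig", function(object) {
  if (object@channel2Coupling < 0 || object@channel2Coupling > 1) {
    return("channel2Coupling must lie in [0, 1]")
  }
  if (object@treadmillSpeed < 0) return("treadmillSpeed must be nonnegative")
  if (object@nFrames < 2L) return("need at least 2 frames")
  if (object@pixelSize <= 0 || object@frameInterval <= 0) {
    return("pixelSize and frameInterval must be positive")
  }
  if (object@psfSigma < 0 || object@readNoiseSd < 0 || object@noiseGain < 0) {
    return("psfSigma, noiseGain and readNoiseSd must be nonnegative")
  }
  TRUE
})

#' Build a FilamentMovieConfig
#'
#' Defaults emulate a treadmilling filament network imaged at one frame per
#' 2 s with 106 nm pixels.
#'
#' @param nFilaments count.
#' @param treadmillSpeed um/s.
#' @param filamentLength um.
#' @param psfSigma um.
#' @param channel2Coupling fraction in \[0, 1\].
#' @param noiseGain Poisson gain (0 = no shot noise).
#' @param readNoiseSd intensity units.
#' @param pixelSize um/px.
#' @param frameInterval s.
#' @param nFrames count.
#' @param fovPixels image side, px.
#' @param seed integer seed.
#' @return A [FilamentMovieConfig-class] object.
#' @export
filamentMovieConfig <- function(nFilaments = 30, treadmillSpeed = 0.04,
                                filamentLength = 2, psfSigma = 0.15,
                                channel2Coupling = 1, noiseGain = 200,
                                readNoiseSd = 0.01, pixelSize = 0.106,
                                frameInterval = 2, nFrames = 20,
                                fovPixels = 64, seed = 1L) {
  new("FilamentMovieConfig", nFilaments = as.integer(nFilaments),
      treadmillSpeed = as.numeric(treadmillSpeed),
      filamentLength = as.numeric(filamentLength),
      psfSigma = as.numeric(psfSigma),
      channel2Coupling = as.numeric(channel2Coupling),
      noiseGain = as.numeric(noiseGain), readNoiseSd = as.numeric(readNoiseSd),
      pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval), nFrames = as.integer(nFrames),
      fovPixels = as.integer(fovPixels), seed = as.integer(seed))
}
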