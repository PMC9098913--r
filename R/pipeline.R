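# Configuration-driven pipeline runner: executes named analysis stages in
# order, writes tables/JSON into an output directory and records a manifest
# (package version, full config echo, seed, output checksums) so that a run
# is reproducible from its manifest alone.

pipelineStages <- c("simulate_tracks", "confine", "dwell_lifetime",
                    "filament_coloc", "frap", "hill", "packing")

mergeParams <- function(defaults, params, stage) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in stage '%s': %s", stage,
                 paste(unknown, collapse = ", ")))
  }
  defaults[names(params)] <- params
  defaults
}

#' Run a configured analysis pipeline
#'
#' The configuration (YAML file or list) carries a seed, an output
#' directory and an ordered list of stages, each a list with a `name` and
#' stage parameters. Supported stages: `simulate_tracks` (two-state track
#' simulation; writes tracks and ground truth CSVs), `confine`
#' (packing-coefficient confinement analysis of the simulated or a given
#' track CSV; writes events CSV + stats JSON), `dwell_lifetime` (dwell
#' simulation + photobleach-corrected lifetime; writes JSON),
#' `filament_coloc` (dual-colour movie simulation + PCC/PCC_diff; writes
#' CSV), `frap` (profile simulation + diffusion/exchange fit; writes JSON),
#' `hill` (Hill fit of a concentration-response CSV; writes JSON) and
#' `packing` (membrane packing geometry; writes JSON). Unknown top-level
#' keys, stage names or stage parameters are rejected before any stage
#' runs. Reruns with the same config and seed are deterministic.
#'
#' @param config path to a YAML config or an equivalent list.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "output_dir", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$output_dir)) stop("config needs output_dir")
  if (is.null(config$stages) || !length(config$stages)) {
    stop("config needs a non-empty stages list")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  for (st in config$stages) {
    if (is.null(st$name) || !st$name %in% pipelineStages) {
      stop("unknown stage name: ", if (is.null(st$name)) "<missing>" else
        st$name, " (supported: ", paste(pipelineStages, collapse = ", "), ")")
    }
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    params <- st[setdiff(names(st), "name")]
    message(sprintf("[stage %d/%d] %s  %s", si, length(config$stages),
                    st$name,
                    paste(names(params), unlist(lapply(params, format)),
                          sep = "=", collapse = " ")))
    res <- tryCatch(
      runStage(st$name, params, seed + si, config$output_dir, state),
      error = function(e) {
        stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                     st$name, conditionMessage(e), config$output_dir),
             call. = FALSE)
      })
    outputs <- c(outputs, res)
  }
  manifest <- list(
    package = "SLBdynamics",
    version = as.character(utils::packageVersion("SLBdynamics")),
    seed = seed,
    config = config,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  mf <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

runStage <- function(name, params, seed, outDir, state) {
  switch(name,
    simulate_tracks = {
      p <- mergeParams(list(n_molecules = 50, fov_size = 10, d_free = 0.2,
                            d_trapped = 0.002, k_bind = 0.3, k_unbind = 1.5,
                            crossing_probability = 1, frame_interval = 0.051,
                            n_frames = 400, localization_noise_sd = 0.02),
                       params, name)
      sim <- simulateTwoStateTracks(twoStateSimConfig(
        nMolecules = p$n_molecules, fovSize = p$fov_size, dFree = p$d_free,
        dTrapped = p$d_trapped, kBind = p$k_bind, kUnbind = p$k_unbind,
        crossingProbability = p$crossing_probability,
        frameInterval = p$frame_interval, nFrames = p$n_frames,
        localizationNoiseSd = p$localization_noise_sd, seed = seed))
      state$tracks <- sim$tracks
      tp <- file.path(outDir, "tracks.csv")
      gp <- file.path(outDir, "truth_events.csv")
      writeTracks(sim$tracks, tp)
      utils::write.csv(sim$truth, gp, row.names = FALSE)
      c(tp, gp)
    },
    confine = {
      p <- mergeParams(list(tracks_csv = NULL, frame_interval = NULL,
                            p_thresh = 1000, t_thresh = 0.25,
                            min_duration = 1), params, name)
      tracks <- if (!is.null(p$tracks_csv)) {
        readTracks(p$tracks_csv, "csv", frameInterval = p$frame_interval)
      } else if (!is.null(state$tracks)) {
        state$tracks
      } else {
        stop("no tracks: run simulate_tracks first or give tracks_csv")
      }
      tracks <- filterTracks(tracks, minDuration = p$min_duration)
      events <- confinementAnalysis(tracks, pThresh = p$p_thresh,
                                    tThresh = p$t_thresh)
      stats <- confinementStats(events, tracks)
      ep <- file.path(outDir, "confinement_events.csv")
      sp <- file.path(outDir, "confinement_stats.json")
      utils::write.csv(events, ep, row.names = FALSE)
      jsonlite::write_json(stats[c("tau", "tauStderr", "confinedFraction",
                                   "nEvents")],
                           sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(ep, sp)
    },
    dwell_lifetime = {
      p <- mergeParams(list(k_off_true = 0.05, bleach_rate = 4,
                            integration_time = 0.05,
                            lapse_intervals = c(0.125, 0.25, 0.5, 1, 2),
                            n_molecules_per_interval = 2000), params, name)
      sets <- simulateDwellTracks(dwellSimConfig(
        kOffTrue = p$k_off_true, bleachRate = p$bleach_rate,
        integrationTime = p$integration_time,
        lapseIntervals = as.numeric(unlist(p$lapse_intervals)),
        nMoleculesPerInterval = p$n_molecules_per_interval, seed = seed))
      fit <- bleachCorrectedLifetime(sets)
      lp <- file.path(outDir, "lifetime.json")
      jsonlite::write_json(list(params = as.list(fitParams(fit)),
                                stderr = as.list(fitStderr(fit)),
                                converged = isConverged(fit)),
                           lp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      lp
    },
    filament_coloc = {
      p <- mergeParams(list(coupling = 1, treadmill_speed = 0.04,
                            n_frames = 12, lag_frames = 1), params, name)
      mov <- simulateFilamentMovie(filamentMovieConfig(
        channel2Coupling = p$coupling, treadmillSpeed = p$treadmill_speed,
        nFrames = p$n_frames, seed = seed))
      pcc <- vapply(seq_len(p$n_frames), function(i) {
        pearsonCC(frames(mov$channel1)[, , i], frames(mov$channel2)[, , i],
                  roi = centralRoi(dim(frames(mov$channel1))[1:2]))
      }, numeric(1))
      pd <- pccDiff(mov$channel1, mov$channel2, lagFrames = p$lag_frames)
      cp <- file.path(outDir, "coloc.csv")
      utils::write.csv(
        data.frame(frame = seq_len(p$n_frames) - 1L, pcc = pcc,
                   pcc_diff = c(pd$perFrame,
                                rep(NA, p$n_frames - length(pd$perFrame)))),
        cp, row.names = FALSE)
      cp
    },
    frap = {
      p <- mergeParams(list(d_coeff = 0.14, k_off = 0.04, noise_sd = 0.02,
                            n_times = 12), params, name)
      prof <- simulateFrapProfiles(
        dCoeff = p$d_coeff, kOff = p$k_off, domainLength = 20,
        bleachWindow = c(7, 13), bleachDepth = 0.9,
        times = seq(0.5, by = 2, length.out = p$n_times),
        noiseSd = p$noise_sd, seed = seed)
      fit <- fitFrap(prof)
      fp <- file.path(outDir, "frap_fit.json")
      jsonlite::write_json(list(params = as.list(fitParams(fit)),
                                stderr = as.list(fitStderr(fit)),
                                converged = isConverged(fit)),
                           fp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      fp
    },
    hill = {
      p <- mergeParams(list(curve_csv = NULL, model = "hill_qcmd"), params,
                       name)
      series <- if (!is.null(p$curve_csv)) {
        d <- utils::read.csv(p$curve_csv)
        BindingSeries(d$concentration_uM, d$response)
      } else {
        simulateBindingCurve("hill_qcmd",
                             list(S = 0, E = -30, n = 1, k = 0.21),
                             concentrations = c(0.05, 0.1, 0.2, 0.4, 0.8,
                                                1.6),
                             noiseSd = 0.02, seed = seed)
      }
      fit <- if (p$model == "hill_qcmd") fitHillQcmd(series) else
        fitHillMst(series)
      hp <- file.path(outDir, "hill_fit.json")
      jsonlite::write_json(list(model = p$model,
                                params = as.list(fitParams(fit)),
                                stderr = as.list(fitStderr(fit)),
                                converged = isConverged(fit)),
                           hp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      hp
    },
    packing = {
      p <- mergeParams(list(footprint_nm2 = 30, lipid_area_nm2 = 0.5),
                       params, name)
      res <- maxPacking(p$footprint_nm2, p$lipid_area_nm2)
      pp <- file.path(outDir, "packing.json")
      jsonlite::write_json(res, pp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      pp
    },
    stop("unknown stage: ", name))
}
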