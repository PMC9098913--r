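# Seeded generators of synthetic imaging data: dual-colour treadmilling
# filament movies, FRAP recovery profiles from the reaction-diffusion
# forward model, acceptor-photobleaching FRET traces, and binding curves.

#' Simulate a dual-colour movie of treadmilling filaments
#'
#' Channel 1 renders the line density of straight filaments whose front
#' advances and rear retracts at the treadmilling speed (constant length, so
#' individual positions appear to translocate by subunit turnover), sampled
#' onto the pixel grid, convolved with a Gaussian PSF and noised with a
#' Poisson photon gain plus Gaussian read noise. Channel 2 mixes a fraction
#' `channel2Coupling` of the channel-1 density with a homogeneous membrane
#' background of equal mean before applying the same PSF and noise,
#' emulating a second protein that either rides on the filaments or binds
#' the membrane independently. Filaments wrap around the field of view.
#'
#' @param config A [FilamentMovieConfig-class] (see
#'   [filamentMovieConfig()]).
#' @return list of two [ImageSeries-class] objects, `channel1` and
#'   `channel2`.
#' @examples
#' mov <- simulateFilamentMovie(filamentMovieConfig(nFrames = 3, seed = 5))
#' pearsonCC(frames(mov$channel1)[, , 1], frames(mov$channel2)[, , 1])
#' @export
simulateFilamentMovie <- function(config) {
  stopifnot(is(config, "FilamentMovieConfig"))
  validObject(config)
  npx <- config@fovPixels
  px <- config@pixelSize
  L <- npx * px
  withSeed(config@seed, {
    nf <- config@nFilaments
    ax <- runif(nf, 0, L)
    ay <- runif(nf, 0, L)
    theta <- runif(nf, 0, 2 * pi)
    ux <- cos(theta); uy <- sin(theta)
    sampleStep <- px / 2
    nSamp <- max(2L, ceiling(config@filamentLength / sampleStep))
    renderDensity <- function(tSec) {
      s <- config@treadmillSpeed * tSec
      img <- matrix(0, npx, npx)
      for (i in seq_len(nf)) {
        d <- seq(s, s + config@filamentLength, length.out = nSamp)
        xs <- (ax[i] + ux[i] * d) %% L
        ys <- (ay[i] + uy[i] * d) %% L
        cx <- pmin(npx, floor(xs / px) + 1L)
        cy <- pmin(npx, floor(ys / px) + 1L)
        for (j in seq_len(nSamp)) img[cy[j], cx[j]] <- img[cy[j], cx[j]] + 1
      }
      img
    }
    addNoise <- function(img) {
      if (config@noiseGain > 0) {
        img <- rpois(length(img), lambda = config@noiseGain * img) /
          config@noiseGain
        img <- matrix(img, npx, npx)
      }
      if (config@readNoiseSd > 0) {
        img <- img + matrix(rnorm(npx * npx, 0, config@readNoiseSd),
                            npx, npx)
      }
      pmax(img, 0)
    }
    sig <- config@psfSigma / px
    ch1 <- array(0, dim = c(npx, npx, config@nFrames))
    ch2 <- array(0, dim = c(npx, npx, config@nFrames))
    cpl <- config@channel2Coupling
    for (f in seq_len(config@nFrames)) {
      dens <- renderDensity((f - 1L) * config@frameInterval)
      base <- gaussianBlur(dens, sig)
      ch1[, , f] <- addNoise(base)
      mix <- cpl * dens + (1 - cpl) * mean(dens)
      ch2[, , f] <- addNoise(gaussianBlur(mix, sig))
    }
    list(channel1 = ImageSeries(ch1, px, config@frameInterval, "channel1"),
         channel2 = ImageSeries(ch2, px, config@frameInterval, "channel2"))
  })
}

#' Simulate FRAP recovery profiles with known ground truth
#'
#' Forward-integrates the 1D diffusion + exchange model (the same
#' reflecting-boundary Crank-Nicolson scheme used by [fitFrap()]) from a
#' step-bleached initial profile and adds Gaussian noise. The ground-truth
#' parameters are recorded in the returned object.
#'
#' @param dCoeff lateral diffusion coefficient, um^2/s.
#' @param kOff exchange (off-binding) rate, 1/s.
#' @param domainLength profile length, um.
#' @param bleachWindow c(x0, x1) extent of the bleached region, um, inside
#'   the domain.
#' @param bleachDepth bleached fraction in \[0, 1\].
#' @param times output times since bleach, s.
#' @param noiseSd Gaussian noise sd as a fraction of the pre-bleach level.
#' @param seed integer RNG seed.
#' @param nx number of spatial samples (default 120).
#' @param nSub time sub-steps per output interval (default 16).
#' @return A [RecoveryProfile-class] with `groundTruth` filled in.
#' @export
simulateFrapProfiles <- function(dCoeff, kOff, domainLength, bleachWindow,
                                 bleachDepth, times, noiseSd = 0, seed = 1L,
                                 nx = 120L, nSub = 16L) {
  if (domainLength <= 0) stop("domainLength must be positive")
  if (bleachDepth < 0 || bleachDepth > 1) {
    stop("bleachDepth must lie in [0, 1]")
  }
  if (bleachWindow[1] < 0 || bleachWindow[2] > domainLength ||
      bleachWindow[1] >= bleachWindow[2]) {
    stop("bleachWindow must lie inside the domain")
  }
  if (dCoeff < 0 || kOff < 0) stop("dCoeff and kOff must be nonnegative")
  dx <- domainLength / nx
  positions <- (seq_len(nx) - 0.5) * dx
  init <- ifelse(positions >= bleachWindow[1] & positions <= bleachWindow[2],
                 1 - bleachDepth, 1)
  allT <- c(0, times)
  prof <- frapForwardModel(dCoeff, kOff, positions, allT, init, nSub = nSub)
  prof <- prof[, -1, drop = FALSE]
  withSeed(seed, {
    if (noiseSd > 0) {
      prof <- prof + matrix(rnorm(length(prof), 0, noiseSd), nrow(prof))
    }
    RecoveryProfile(positions = positions, times = times, intensities = prof,
                    bleachWindow = bleachWindow,
                    groundTruth = list(dCoeff = dCoeff, kOff = kOff,
                                       bleachDepth = bleachDepth,
                                       noiseSd = noiseSd))
  })
}

#' Simulate an acceptor-photobleaching FRET trace
#'
#' The donor jumps at the bleach frame from its pre level to
#' pre / (1 - E); the acceptor drops to background. Gaussian noise is
#' scaled to the donor pre level.
#'
#' @param eTrue true FRET efficiency, fraction in \[0, 1).
#' @param donorPreLevel pre-bleach donor intensity.
#' @param bleachFrame 1-based index of the first post-bleach frame.
#' @param nFrames trace length.
#' @param noiseSd noise sd as a fraction of the donor pre level.
#' @param seed integer RNG seed.
#' @param frameInterval s (default 1).
#' @param acceptorPreLevel pre-bleach acceptor intensity (default: donor
#'   pre level).
#' @param background c(donor, acceptor) offsets added to the trace.
#' @return A [FretTrace-class].
#' @export
simulateFretTrace <- function(eTrue, donorPreLevel, bleachFrame, nFrames,
                              noiseSd = 0, seed = 1L, frameInterval = 1,
                              acceptorPreLevel = donorPreLevel,
                              background = c(0, 0)) {
  if (eTrue < 0 || eTrue >= 1) stop("eTrue must lie in [0, 1)")
  if (bleachFrame < 2L || bleachFrame > nFrames) {
    stop("bleachFrame must lie within the trace")
  }
  post <- donorPreLevel / (1 - eTrue)
  donor <- c(rep(donorPreLevel, bleachFrame - 1L),
             rep(post, nFrames - bleachFrame + 1L))
  acceptor <- c(rep(acceptorPreLevel, bleachFrame - 1L),
                rep(0, nFrames - bleachFrame + 1L))
  withSeed(seed, {
    if (noiseSd > 0) {
      donor <- donor + rnorm(nFrames, 0, noiseSd * donorPreLevel)
      acceptor <- pmax(0, acceptor + rnorm(nFrames, 0,
                                           noiseSd * donorPreLevel))
    }
    FretTrace(times = (seq_len(nFrames) - 1L) * frameInterval,
              donor = donor + background[1],
              acceptor = acceptor + background[2],
              bleachFrame = bleachFrame, background = background)
  })
}

#' Simulate a binding curve from a Hill model
#'
#' Evaluates the named Hill form at the given concentrations and adds
#' Gaussian noise scaled to the response range.
#'
#' @param model `"hill_qcmd"` (params S, E, n, k) or `"hill_mst"` (params
#'   U, B, EC50, n).
#' @param params named list/vector of model parameters.
#' @param concentrations uM, strictly increasing.
#' @param noiseSd noise sd as a fraction of the response range.
#' @param seed integer RNG seed.
#' @return A [BindingSeries-class]; the true parameters are attached as
#'   attribute `groundTruth`.
#' @export
simulateBindingCurve <- function(model = c("hill_qcmd", "hill_mst"), params,
                                 concentrations, noiseSd = 0, seed = 1L) {
  model <- match.arg(model)
  params <- as.list(params)
  y <- if (model == "hill_qcmd") {
    hillQcmd(concentrations, params$S, params$E, params$n, params$k)
  } else {
    hillMst(concentrations, params$U, params$B, params$EC50, params$n)
  }
  withSeed(seed, {
    if (noiseSd > 0) {
      span <- max(abs(diff(range(y))), 1e-12)
      y <- y + rnorm(length(y), 0, noiseSd * span)
    }
    out <- BindingSeries(concentrations, y)
    attr(out, "groundTruth") <- params
    out
  })
}
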