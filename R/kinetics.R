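# Single-molecule residence-time and diffusion analysis: apparent off-rate
# per time-lapse interval, photobleach-corrected lifetime from the
# multi-interval linearization, and per-track MSD diffusion estimation.

#' Apparent unbinding rate from observed dwell durations
#'
#' Dwell durations observed at one lapse interval are multiples of that
#' interval, so the exponential survival model becomes geometric in the
#' frame count F: P(F = m) = (1-q)^(m-1) q with
#' q = 1 - exp(-k_eff tau_tl). The maximum-likelihood estimate is
#' q_hat = 1 / mean(F), giving k_eff = -log(1 - q_hat)/tau_tl; this is the
#' exponential-rate MLE corrected for the one-frame minimum observable
#' duration (the continuous-time shortcut 1/(mean - tau_tl) is its small-q
#' limit). Standard error by the delta method from the Fisher information
#' of q.
#'
#' @param dataset A [DwellDataset-class] with at least 20 durations.
#' @return A [FitResult-class] with `k_eff` (1/s). Datasets where every
#'   molecule survived exactly one frame are unidentifiable and returned
#'   flagged.
#' @export
apparentOffRate <- function(dataset) {
  stopifnot(is(dataset, "DwellDataset"))
  tl <- dataset@lapseInterval
  f <- round(dataset@durations / tl)
  if (length(f) < 20L) stop("need at least 20 dwell durations")
  q <- 1 / mean(f)
  if (q >= 1) {
    return(FitResult(params = c(k_eff = NA_real_),
                     modelName = "dwell_rate_mle", converged = FALSE,
                     diagnostics = list(
                       message = "all dwells lasted one frame; rate unidentifiable")))
  }
  kEff <- -log(1 - q) / tl
  seQ <- sqrt(q^2 * (1 - q) / length(f))
  seK <- seQ / ((1 - q) * tl)
  FitResult(params = c(k_eff = kEff), stderr = c(k_eff = seK),
            modelName = "dwell_rate_mle",
            diagnostics = list(n = length(f), q = q))
}

#' Photobleach-corrected lifetime from per-interval rates
#'
#' Core regression of the multi-interval correction: with per-frame
#' disappearance combining unbinding over the lapse interval and bleaching
#' over the exposure, k_eff tau_tl = k_off tau_tl + k_b tau_int. Regressing
#' k_eff tau_tl on tau_tl therefore yields the true off-rate as the slope
#' (the corrected lifetime is its inverse) and the bleaching number
#' k_b tau_int as the intercept.
#'
#' @param kEff apparent rates per interval, 1/s.
#' @param lapseIntervals matching lapse intervals, s (>= 3 distinct).
#' @param kEffSe optional standard errors of `kEff`; when given, the
#'   regression is weighted by the known per-point variances and the
#'   parameter standard errors are propagated from them (instead of from
#'   the residual scatter of as few as 3-5 points).
#' @return A [FitResult-class] with `k_off` (1/s), `lifetime` (s),
#'   `bleach_number` (dimensionless). A negative fitted slope (bleaching-
#'   dominated data) is returned flagged.
#' @export
lifetimeFromRates <- function(kEff, lapseIntervals, kEffSe = NULL) {
  if (length(unique(lapseIntervals)) < 3L) {
    stop("need at least 3 distinct lapse intervals")
  }
  y <- kEff * lapseIntervals
  x <- lapseIntervals
  if (is.null(kEffSe)) {
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(suppressWarnings(summary(fit)))
    kOff <- unname(cf["x", "Estimate"])
    kOffSe <- unname(cf["x", "Std. Error"])
    bn <- unname(cf["(Intercept)", "Estimate"])
    bnSe <- unname(cf["(Intercept)", "Std. Error"])
    r2 <- suppressWarnings(summary(fit))$r.squared
  } else {
    w <- 1 / (kEffSe * lapseIntervals)^2
    xw <- sum(w * x) / sum(w)
    yw <- sum(w * y) / sum(w)
    sxx <- sum(w * (x - xw)^2)
    kOff <- sum(w * (x - xw) * (y - yw)) / sxx
    bn <- yw - kOff * xw
    kOffSe <- sqrt(1 / sxx)
    bnSe <- sqrt(1 / sum(w) + xw^2 / sxx)
    pred <- bn + kOff * x
    r2 <- rSquaredOf(y, pred)
  }
  flagged <- kOff <= 0
  lifetime <- if (flagged) NA_real_ else 1 / kOff
  FitResult(params = c(k_off = kOff, lifetime = lifetime, bleach_number = bn),
            stderr = c(k_off = kOffSe,
                       lifetime = if (flagged) NA_real_ else kOffSe / kOff^2,
                       bleach_number = bnSe),
            rSquared = r2,
            modelName = "bleach_corrected_lifetime", converged = !flagged,
            diagnostics = if (flagged) {
              list(message = "negative slope: bleaching-dominated, lifetime unresolvable at these intervals")
            } else list())
}

#' Photobleach-corrected membrane lifetime from multi-interval dwell data
#'
#' Estimates the apparent rate of each dataset with [apparentOffRate()] and
#' feeds them to [lifetimeFromRates()].
#'
#' @param datasets list of [DwellDataset-class] objects at >= 3 distinct
#'   lapse intervals.
#' @return A [FitResult-class]; see [lifetimeFromRates()].
#' @examples
#' sets <- simulateDwellTracks(dwellSimConfig(kOffTrue = 0.05,
#'          nMoleculesPerInterval = 2000, seed = 2))
#' fitParams(bleachCorrectedLifetime(sets))
#' @export
bleachCorrectedLifetime <- function(datasets) {
  stopifnot(length(datasets) >= 3L)
  fits <- lapply(datasets, apparentOffRate)
  kEff <- vapply(fits, function(f) fitParams(f)[["k_eff"]], numeric(1))
  kEffSe <- vapply(fits, function(f) fitStderr(f)[["k_eff"]], numeric(1))
  tl <- vapply(datasets, function(d) d@lapseInterval, numeric(1))
  lifetimeFromRates(kEff, tl, kEffSe = kEffSe)
}

#' Time-averaged mean squared displacement of a track
#'
#' @param td data.frame of one track (columns `frame`, `x_um`, `y_um`,
#'   `t_s`) or a single-track [TrackSet-class].
#' @param maxLag largest lag in frames.
#' @return data.frame with `lag_s`, `msd` (um^2) and `n_pairs`; lags that
#'   span frame gaps use only gap-free pairs.
#' @export
msdCurve <- function(td, maxLag) {
  if (is(td, "TrackSet")) td <- trackData(td)
  if (length(unique(td$track_id)) > 1L) stop("msdCurve expects one track")
  dtAll <- diff(td$t_s) / diff(td$frame)
  dt <- stats::median(dtAll)
  out <- lapply(seq_len(maxLag), function(l) {
    i <- seq_len(nrow(td) - l)
    ok <- td$frame[i + l] - td$frame[i] == l
    if (!any(ok)) return(NULL)
    d2 <- (td$x_um[i + l][ok] - td$x_um[i][ok])^2 +
          (td$y_um[i + l][ok] - td$y_um[i][ok])^2
    data.frame(lag_s = l * dt, msd = mean(d2), n_pairs = sum(ok))
  })
  do.call(rbind, out)
}

#' Per-track diffusion coefficient from an MSD fit
#'
#' Fits MSD = 4 D tau + offset over short lags of the time-averaged MSD;
#' the intercept absorbs localization noise and D is floored at zero.
#' Tracks shorter than `minTrackDuration` are skipped (returned flagged
#' with the reason) -- short-lived molecules yield unreliable MSD curves.
#'
#' @param track single-track [TrackSet-class] or track data.frame.
#' @param maxLagFraction fraction of the track length used as maximum lag
#'   (default 0.25; at least 3 lags are always used). For long tracks a
#'   much smaller fraction is statistically preferable: long-lag values of
#'   a time-averaged MSD are strongly correlated and inflate the variance
#'   of the fitted D.
#' @param minTrackDuration minimum track duration, s (default 0.4).
#' @param weightByPairs weight the linear fit by the number of displacement
#'   pairs per lag (default FALSE: ordinary least squares).
#' @return A [FitResult-class] with `D` (um^2/s) and `offset` (um^2);
#'   skipped tracks carry `converged = FALSE` and a reason in diagnostics.
#' @export
msdDiffusion <- function(track, maxLagFraction = 0.25,
                         minTrackDuration = 0.4, weightByPairs = FALSE) {
  td <- if (is(track, "TrackSet")) trackData(track) else track
  if (length(unique(td$track_id)) > 1L) {
    stop("msdDiffusion expects one track; use lapply over split tracks")
  }
  duration <- max(td$t_s) - min(td$t_s)
  if (duration < minTrackDuration) {
    return(FitResult(params = c(D = NA_real_, offset = NA_real_),
                     modelName = "msd_linear", converged = FALSE,
                     diagnostics = list(
                       reason = sprintf("track duration %.3g s below %.3g s",
                                        duration, minTrackDuration))))
  }
  maxLag <- max(3L, floor((nrow(td) - 1L) * maxLagFraction))
  maxLag <- min(maxLag, nrow(td) - 1L)
  mc <- msdCurve(td, maxLag)
  if (is.null(mc) || nrow(mc) < 2L) {
    return(FitResult(params = c(D = NA_real_, offset = NA_real_),
                     modelName = "msd_linear", converged = FALSE,
                     diagnostics = list(reason = "too few valid lags")))
  }
  w <- if (weightByPairs) mc$n_pairs else NULL
  fit <- stats::lm(msd ~ lag_s, data = mc, weights = w)
  cf <- stats::coef(suppressWarnings(summary(fit)))
  D <- max(0, unname(cf["lag_s", "Estimate"]) / 4)
  FitResult(params = c(D = D, offset = unname(cf["(Intercept)", "Estimate"])),
            stderr = c(D = unname(cf["lag_s", "Std. Error"]) / 4,
                       offset = unname(cf["(Intercept)", "Std. Error"])),
            rSquared = suppressWarnings(summary(fit))$r.squared,
            modelName = "msd_linear",
            diagnostics = list(maxLag = maxLag, curve = mc))
}
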