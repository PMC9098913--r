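# Image-level statistics on dual-colour time-lapse movies: Pearson
# colocalization, differential-image co-treadmilling correlation, temporal
# autocorrelation of the filament pattern, pixel-wise intensity-slope
# regression, and recruitment-rate fitting.

#' Pearson correlation between two images
#'
#' Standard Pearson correlation coefficient over the (ROI) pixels of two
#' equally sized images. Invariant to positive affine transforms of either
#' channel; values span \[-1, 1\].
#'
#' @param imgA,imgB numeric matrices of equal size.
#' @param roi optional pixel rectangle c(x, y, w, h) (0-based, half-open);
#'   NULL uses the full image.
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' a <- matrix(c(1, 2, 3, 4), 2)
#' pearsonCC(a, 3 * a + 7)   # 1
#' @export
pearsonCC <- function(imgA, imgB, roi = NULL) {
  if (!all(dim(imgA) == dim(imgB))) stop("images must have the same shape")
  a <- as.vector(roiPixels(imgA, roi))
  b <- as.vector(roiPixels(imgB, roi))
  if (length(a) < 2L) stop("need at least 2 pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance in at least one channel")
  }
  stats::cor(a, b)
}

#' Per-frame intensity normalization of an image series
#'
#' `frame_mean` divides each frame by its spatial mean, removing global
#' photobleaching from the intensity scale before correlation analysis;
#' `none` returns the input unchanged.
#'
#' @param series An [ImageSeries-class].
#' @param method `"frame_mean"` or `"none"`.
#' @return An [ImageSeries-class] with identical metadata.
#' @export
normalizeSeries <- function(series, method = c("frame_mean", "none")) {
  stopifnot(is(series, "ImageSeries"))
  method <- match.arg(method)
  if (method == "none") return(series)
  f <- frames(series)
  means <- apply(f, 3, mean)
  if (any(means == 0)) stop("cannot normalize: frame with zero mean")
  out <- sweep(f, 3, means, "/")
  ImageSeries(out, pixelSize(series), frameInterval(series),
              channelLabel(series))
}

#' Differential image series (growing-end visualization)
#'
#' Subtracts frames separated by `lagFrames` and clips negative differences
#' to zero, so that only regions of intensity gain -- the growing ends of
#' treadmilling filament bundles -- remain. Output frame i is
#' `max(0, frame(i + lag) - frame(i))`; the series shortens by `lagFrames`.
#'
#' @param series An [ImageSeries-class] with more frames than `lagFrames`.
#' @param lagFrames frame lag (default 1 = consecutive frames).
#' @return An [ImageSeries-class] of T - lag differential frames.
#' @export
differentialSeries <- function(series, lagFrames = 1L) {
  stopifnot(is(series, "ImageSeries"))
  lagFrames <- as.integer(lagFrames)
  tN <- nFrames(series)
  if (lagFrames < 1L || lagFrames >= tN) {
    stop("lagFrames must satisfy 1 <= lag < number of frames")
  }
  f <- frames(series)
  out <- pmax(f[, , (lagFrames + 1L):tN, drop = FALSE] -
              f[, , 1:(tN - lagFrames), drop = FALSE], 0)
  ImageSeries(out, pixelSize(series), frameInterval(series),
              paste0(channelLabel(series), "_diff"))
}

#' Co-treadmilling correlation between differential movies (PCC_diff)
#'
#' Computes the Pearson correlation per frame pair between the differential
#' versions of two channels. High values mean the growing filament ends in
#' the two channels advance together (co-treadmilling); a second channel
#' that binds the membrane independently of the filaments scores near zero.
#' Frames where either differential image has zero variance (e.g. a static
#' movie) are skipped and counted.
#'
#' @param seriesA,seriesB [ImageSeries-class] objects with equal shape,
#'   frame count and interval.
#' @param lagFrames differential lag (default 1).
#' @param roi pixel rectangle; default central 80% region
#'   ([centralRoi()]).
#' @return list with `perFrame` (per-frame PCC_diff values, NA where
#'   skipped), `mean` (mean over valid frames), `nSkipped`.
#' @export
pccDiff <- function(seriesA, seriesB, lagFrames = 1L, roi = NULL) {
  stopifnot(is(seriesA, "ImageSeries"), is(seriesB, "ImageSeries"))
  if (!all(dim(frames(seriesA)) == dim(frames(seriesB)))) {
    stop("series must have identical shapes and frame counts")
  }
  if (abs(frameInterval(seriesA) - frameInterval(seriesB)) > 1e-12) {
    stop("series must share the frame interval")
  }
  if (is.null(roi)) roi <- centralRoi(dim(frames(seriesA))[1:2])
  da <- frames(differentialSeries(seriesA, lagFrames))
  db <- frames(differentialSeries(seriesB, lagFrames))
  vals <- vapply(seq_len(dim(da)[3]), function(i) {
    tryCatch(pearsonCC(da[, , i], db[, , i], roi = roi),
             error = function(e) NA_real_)
  }, numeric(1))
  list(perFrame = vals, mean = mean(vals, na.rm = TRUE),
       nSkipped = sum(is.na(vals)))
}

#' Temporal autocorrelation of an image series
#'
#' Pearson correlation between the first frame and every subsequent frame
#' with increasing lag; persistent structures decay slowly, fast filament
#' reorganization decays quickly. The lag-0 value is 1 by definition.
#'
#' @param series An [ImageSeries-class] with at least 3 frames.
#' @param roi pixel rectangle; default central 80% region.
#' @param averaged if TRUE, average the correlation over all frame pairs at
#'   each lag instead of anchoring to frame 0 (more noise-robust variant).
#' @return A [CorrelationCurve-class].
#' @export
temporalAutocorrelation <- function(series, roi = NULL, averaged = FALSE) {
  stopifnot(is(series, "ImageSeries"))
  tN <- nFrames(series)
  if (tN < 3L) stop("need at least 3 frames")
  if (is.null(roi)) roi <- centralRoi(dim(frames(series))[1:2])
  f <- frames(series)
  vals <- numeric(tN)
  vals[1] <- 1
  for (k in 1:(tN - 1L)) {
    vals[k + 1L] <- if (!averaged) {
      pearsonCC(f[, , 1], f[, , k + 1L], roi = roi)
    } else {
      mean(vapply(1:(tN - k), function(i) {
        pearsonCC(f[, , i], f[, , i + k], roi = roi)
      }, numeric(1)))
    }
  }
  CorrelationCurve(lags = (0:(tN - 1L)) * frameInterval(series),
                   values = pmin(1, pmax(-1, vals)))
}

#' Fit a monoexponential decay to a correlation curve
#'
#' Least-squares fit of y = a exp(-b t) + k; the decay half time is
#' ln(2)/b. Degenerate inputs (flat curves, unidentifiable decay) return a
#' flagged result instead of failing.
#'
#' @param curve A [CorrelationCurve-class] with at least 4 points, or a
#'   data.frame with columns `lags`/`values`.
#' @return A [FitResult-class] with parameters `a`, `b` (1/s), `k`, and
#'   `half_time` (s).
#' @export
fitExpDecay <- function(curve) {
  if (is(curve, "CorrelationCurve")) {
    t <- curve@lags; y <- curve@values
  } else {
    t <- curve$lags; y <- curve$values
  }
  if (length(t) < 4L) stop("need at least 4 points")
  k0 <- min(y)
  a0 <- max(y) - k0
  b0 <- {
    pos <- y - k0 > (max(y) - k0) * 0.05
    if (sum(pos) > 2 && a0 > 0) {
      sl <- stats::coef(stats::lm(log(y[pos] - k0 + 1e-12) ~ t[pos]))[2]
      max(1e-4, -sl)
    } else 1e-3
  }
  fn <- function(p) p[["a"]] * exp(-p[["b"]] * t) + p[["k"]] - y
  fit <- lmFit(c(a = a0, b = unname(b0), k = k0), fn,
               modelName = "monoexp_decay", obs = y)
  params <- fitParams(fit)
  se <- fitStderr(fit)
  flagged <- !isConverged(fit) || !is.finite(se[["b"]]) ||
    params[["b"]] <= 0 || se[["b"]] > abs(params[["b"]])
  params["half_time"] <- log(2) / params[["b"]]
  se["half_time"] <- if (is.finite(se[["b"]])) {
    log(2) / params[["b"]]^2 * se[["b"]]
  } else NA_real_
  FitResult(params = params, stderr = se, rSquared = fit@rSquared,
            modelName = "monoexp_decay", converged = !flagged,
            diagnostics = fit@diagnostics)
}

#' Pixel-wise intensity-slope regression between two channels
#'
#' Ordinary least squares of channel-B pixel intensity on channel-A pixel
#' intensity (y = k x + d) after optional per-channel background
#' subtraction. The slope estimates the relative binding capacity of the
#' structure in channel A for the protein in channel B (e.g. FtsA molecules
#' per FtsZ filament density).
#'
#' @param imgA,imgB numeric matrices of equal shape (A is the regressor).
#' @param roi optional pixel rectangle.
#' @param background `"percentile_1"` subtracts each channel's 1st
#'   percentile (camera offset removal); `"none"` uses raw intensities.
#' @return A [FitResult-class] with `k` (slope) and `d` (offset).
#' @export
intensitySlope <- function(imgA, imgB, roi = NULL,
                           background = c("percentile_1", "none")) {
  background <- match.arg(background)
  if (!all(dim(imgA) == dim(imgB))) stop("images must have the same shape")
  a <- as.vector(roiPixels(imgA, roi))
  b <- as.vector(roiPixels(imgB, roi))
  if (length(a) < 10L) stop("need at least 10 pixels")
  if (background == "percentile_1") {
    a <- a - stats::quantile(a, 0.01, names = FALSE)
    b <- b - stats::quantile(b, 0.01, names = FALSE)
  }
  if (stats::sd(a) == 0) stop("zero variance in channel A")
  fit <- stats::lm(b ~ a)
  cf <- stats::coef(suppressWarnings(summary(fit)))
  FitResult(params = c(k = unname(cf["a", "Estimate"]),
                       d = unname(cf["(Intercept)", "Estimate"])),
            stderr = c(k = unname(cf["a", "Std. Error"]),
                       d = unname(cf["(Intercept)", "Std. Error"])),
            rSquared = suppressWarnings(summary(fit))$r.squared,
            modelName = "intensity_slope")
}

#' Recruitment-rate fit to a colocalization time course
#'
#' Fits y = a (1 - exp(-b t)) + c to PCC values recorded after protein
#' addition at t = 0; `b` is reported as the recruitment rate (1/s). Flat
#' series leave `b` unidentifiable and return a flagged result.
#'
#' @param pccVsTime data.frame with columns `t_s` and `value` (>= 4 rows).
#' @return A [FitResult-class] with `a`, `b` (1/s), `c`.
#' @export
recruitmentRate <- function(pccVsTime) {
  t <- pccVsTime$t_s; y <- pccVsTime$value
  if (length(t) < 4L) stop("need at least 4 time points")
  c0 <- y[1]
  a0 <- max(y) - c0
  b0 <- 1 / max(t[2], mean(t))
  fn <- function(p) p[["a"]] * (1 - exp(-p[["b"]] * t)) + p[["c"]] - y
  fit <- lmFit(c(a = a0, b = b0, c = c0), fn,
               modelName = "recruitment_rate", obs = y)
  params <- fitParams(fit)
  se <- fitStderr(fit)
  flagged <- !isConverged(fit) || !is.finite(se[["b"]]) ||
    params[["b"]] <= 0 || se[["b"]] > abs(params[["b"]])
  FitResult(params = params, stderr = se, rSquared = fit@rSquared,
            modelName = "recruitment_rate", converged = !flagged,
            diagnostics = fit@diagnostics)
}
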