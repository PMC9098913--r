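# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Validate and normalize a pixel ROI c(x, y, w, h), 0-based origin top-left,
# half-open on the right/bottom. Returns an integer vector.
normalizeRoi <- function(roi, dimHW, clip = FALSE) {
  if (is.list(roi)) roi <- unlist(roi[c("x", "y", "w", "h")])
  roi <- as.integer(round(roi))
  if (length(roi) != 4L || any(is.na(roi)) || roi[3] < 1L || roi[4] < 1L) {
    stop("roi must be c(x, y, w, h) with positive width and height")
  }
  names(roi) <- c("x", "y", "w", "h")
  H <- dimHW[1]; W <- dimHW[2]
  if (roi["x"] < 0L || roi["y"] < 0L ||
      roi["x"] + roi["w"] > W || roi["y"] + roi["h"] > H) {
    if (!clip) {
      stop(sprintf("roi (%d, %d, %d, %d) exceeds image bounds %d x %d",
                   roi["x"], roi["y"], roi["w"], roi["h"], W, H))
    }
    warning("roi exceeds image bounds; clipping")
    x0 <- max(roi["x"], 0L); y0 <- max(roi["y"], 0L)
    x1 <- min(roi["x"] + roi["w"], W); y1 <- min(roi["y"] + roi["h"], H)
    roi <- c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
  }
  roi
}

# Extract ROI pixels from a matrix (rows = y, cols = x).
roiPixels <- function(img, roi = NULL) {
  if (is.null(roi)) return(img)
  roi <- normalizeRoi(roi, dim(img))
  img[(roi["y"] + 1L):(roi["y"] + roi["h"]),
      (roi["x"] + 1L):(roi["x"] + roi["w"]), drop = FALSE]
}

#' Centered default region of interest
#'
#' Central rectangle covering a fraction of each image dimension, the
#' default analysis region for image-level statistics (regions in the centre
#' of the stack avoid edge and illumination artefacts).
#'
#' @param dimHW c(height, width) of the image in pixels.
#' @param fraction linear fraction of each dimension to keep (default 0.8).
#' @return Integer ROI c(x, y, w, h), 0-based, half-open.
#' @export
centralRoi <- function(dimHW, fraction = 0.8) {
  h <- max(1L, as.integer(round(dimHW[1] * fraction)))
  w <- max(1L, as.integer(round(dimHW[2] * fraction)))
  y <- as.integer(floor((dimHW[1] - h) / 2))
  x <- as.integer(floor((dimHW[2] - w) / 2))
  c(x = x, y = y, w = w, h = h)
}

# Separable Gaussian blur with reflected edges; sigma in pixels.
gaussianBlur <- function(img, sigmaPx) {
  if (sigmaPx <= 0) return(img)
  r <- max(1L, ceiling(3 * sigmaPx))
  k <- dnorm(seq(-r, r), sd = sigmaPx)
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
  conv1 <- function(v) {
    vv <- pad(v)
    as.numeric(stats::filter(vv, k, sides = 2))[(r + 1):(r + length(v))]
  }
  img <- apply(img, 2, conv1)
  t(apply(t(img), 2, conv1))
}

# Shoelace polygon area for points in hull order.
polygonArea <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# R^2 of predictions vs observations.
rSquaredOf <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

# Wrap minpack.lm::nls.lm with a uniform FitResult interface.
# fn(par) must return the residual vector.
lmFit <- function(par, fn, lower = NULL, upper = NULL, modelName = "",
                  obs = NULL) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(out, "error")) {
    return(FitResult(params = par, modelName = modelName, converged = FALSE,
                     diagnostics = list(message = conditionMessage(out))))
  }
  est <- out$par
  se <- tryCatch({
    s <- summary(out)
    setNames(s$coefficients[, "Std. Error"], names(est))
  }, error = function(e) setNames(rep(NA_real_, length(est)), names(est)))
  r2 <- if (!is.null(obs)) rSquaredOf(obs, obs - out$fvec) else NA_real_
  converged <- out$info %in% 1:4
  atBound <- FALSE
  if (!is.null(lower)) atBound <- atBound || any(est <= lower + 1e-12)
  if (!is.null(upper)) atBound <- atBound || any(est >= upper - 1e-12)
  FitResult(params = unlist(est), stderr = se, rSquared = r2,
            modelName = modelName, converged = converged,
            diagnostics = list(info = out$info, message = out$message,
                               atBound = atBound,
                               deviance = sum(out$fvec^2)))
}
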