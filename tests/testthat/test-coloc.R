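# Colocalization and co-treadmilling statistics.

test_that("pearsonCC matches hand computation and its invariances", {
  a <- matrix(c(1, 3, 2, 4), 2)           # [[1,2],[3,4]] row-wise
  b <- matrix(c(4, 2, 3, 1), 2)           # [[4,3],[2,1]]
  expect_equal(pearsonCC(a, a), 1)
  expect_equal(pearsonCC(a, b), -1)

  set.seed(11)
  for (i in 1:5) {
    x <- matrix(runif(400), 20)
    y <- matrix(runif(400), 20)
    r <- pearsonCC(x, y)
    # positive affine invariance of either channel
    expect_equal(pearsonCC(3 * x + 7, y), r, tolerance = 1e-12)
    expect_equal(pearsonCC(x, 0.2 * y + 100), r, tolerance = 1e-12)
    # antisymmetry under sign flip of one channel
    expect_equal(pearsonCC(max(y) - y + 1, x), -r, tolerance = 1e-12)
  }

  expect_error(pearsonCC(matrix(1, 3, 3), matrix(runif(9), 3)),
               "zero variance")
  expect_error(pearsonCC(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
  # ROI restricts the computation
  x <- matrix(runif(100), 10)
  y <- matrix(runif(100), 10)
  sub <- c(x = 2, y = 3, w = 5, h = 4)
  expect_equal(pearsonCC(x, y, roi = sub),
               cor(as.vector(x[4:7, 3:7]), as.vector(y[4:7, 3:7])))
})

test_that("frame-mean normalization removes global bleaching", {
  const <- ImageSeries(array(5, c(8, 8, 4)), 0.1, 2)
  nc <- normalizeSeries(const, "frame_mean")
  expect_true(all(frames(nc) == 1))

  set.seed(2)
  base <- matrix(runif(64, 1, 2), 8)
  bleach <- exp(-0.2 * (0:4))
  ser <- ImageSeries(array(outer(as.vector(base), bleach), c(8, 8, 5)),
                     0.1, 2)
  ns <- normalizeSeries(ser, "frame_mean")
  m <- apply(frames(ns), 3, mean)
  expect_equal(m, rep(1, 5), tolerance = 1e-12)
  expect_identical(frames(normalizeSeries(ser, "none")), frames(ser))
  zero <- ImageSeries(array(0, c(4, 4, 2)), 0.1, 2)
  expect_error(normalizeSeries(zero, "frame_mean"), "zero mean")
})

test_that("differential images isolate the moving leading edge", {
  static <- ImageSeries(array(runif(64 * 3), c(8, 8, 3)) * 0 + 5, 0.1, 2)
  expect_true(all(frames(differentialSeries(static)) == 0))

  # a single bright pixel marching right one pixel per frame
  f <- array(0, c(5, 5, 3))
  f[3, 1, 1] <- 1; f[3, 2, 2] <- 1; f[3, 3, 3] <- 1
  ser <- ImageSeries(f, 0.1, 2)
  d <- frames(differentialSeries(ser, 1))
  expect_identical(dim(d)[3], 2L)
  expect_equal(which(d[, , 1] > 0), which(f[, , 2] > 0))  # leading edge only
  expect_equal(sum(d[, , 1] > 0), 1L)

  expect_error(differentialSeries(ser, 3), "lag")
})

test_that("PCC_diff separates coupled from uncoupled channels", {
  mov <- simulateFilamentMovie(filamentMovieConfig(nFrames = 8,
                                                   readNoiseSd = 0.02,
                                                   seed = 21))
  self <- pccDiff(mov$channel1, mov$channel1)
  expect_equal(self$mean, 1, tolerance = 1e-12)

  # independent noise movies: mean is within the Pearson null width
  set.seed(3)
  n1 <- ImageSeries(array(runif(32 * 32 * 6), c(32, 32, 6)), 0.1, 2)
  n2 <- ImageSeries(array(runif(32 * 32 * 6), c(32, 32, 6)), 0.1, 2)
  nd <- pccDiff(n1, n2, roi = c(0, 0, 32, 32))
  expect_lt(abs(nd$mean), 3 / sqrt(32 * 32 * 5))

  # treadmilling fast enough for the growth front to advance > 1 px/frame
  coupled <- simulateFilamentMovie(filamentMovieConfig(channel2Coupling = 1,
                                                       treadmillSpeed = 0.12,
                                                       nFrames = 8,
                                                       readNoiseSd = 0.02,
                                                       seed = 22))
  uncoupled <- simulateFilamentMovie(filamentMovieConfig(
    channel2Coupling = 0, treadmillSpeed = 0.12, nFrames = 8,
    readNoiseSd = 0.02, seed = 22))
  high <- pccDiff(coupled$channel1, coupled$channel2)$mean
  low <- pccDiff(uncoupled$channel1, uncoupled$channel2)$mean
  expect_gt(high, 0.5)
  expect_lt(abs(low), 0.15)
})

test_that("PCC and PCC_diff increase with channel coupling", {
  couplings <- c(0, 0.25, 0.5, 0.75, 1)
  pcc <- numeric(5); pcd <- numeric(5)
  for (i in seq_along(couplings)) {
    mov <- simulateFilamentMovie(filamentMovieConfig(
      channel2Coupling = couplings[i], nFrames = 6, readNoiseSd = 0.02,
      seed = 31))
    pcc[i] <- mean(vapply(1:6, function(k) {
      pearsonCC(frames(mov$channel1)[, , k], frames(mov$channel2)[, , k],
                roi = centralRoi(c(64, 64)))
    }, numeric(1)))
    pcd[i] <- pccDiff(mov$channel1, mov$channel2)$mean
  }
  expect_true(all(diff(pcc) > 0))
  expect_true(all(diff(pcd) > 0))
})

test_that("autocorrelation decays faster for faster treadmilling", {
  static <- ImageSeries(array(rep(runif(256), 4), c(16, 16, 4)), 0.1, 2)
  ac <- temporalAutocorrelation(static, roi = c(0, 0, 16, 16))
  expect_equal(ac@values, rep(1, 4), tolerance = 1e-12)

  set.seed(5)
  noise <- ImageSeries(array(runif(16 * 16 * 5), c(16, 16, 5)), 0.1, 2)
  acn <- temporalAutocorrelation(noise, roi = c(0, 0, 16, 16))
  expect_lt(max(abs(acn@values[-1])), 0.25)

  speeds <- c(0.01, 0.03, 0.06, 0.12)
  rates <- vapply(seq_along(speeds), function(i) {
    mov <- simulateFilamentMovie(filamentMovieConfig(
      treadmillSpeed = speeds[i], nFrames = 15, readNoiseSd = 0.02,
      seed = 41))
    fit <- fitExpDecay(temporalAutocorrelation(mov$channel1))
    fitParams(fit)[["b"]]
  }, numeric(1))
  expect_gt(cor(speeds, rates, method = "spearman"), 0)
})

test_that("monoexponential decay fit recovers parameters and half time", {
  t <- seq(0, 100, by = 2)
  y <- 0.8 * exp(-0.05 * t) + 0.2
  fit <- fitExpDecay(CorrelationCurve(t, y))
  expect_true(isConverged(fit))
  p <- fitParams(fit)
  expect_equal(p[["a"]], 0.8, tolerance = 1e-6)
  expect_equal(p[["b"]], 0.05, tolerance = 1e-6)
  expect_equal(p[["k"]], 0.2, tolerance = 1e-6)
  expect_equal(p[["half_time"]], log(2) / 0.05, tolerance = 1e-6)

  flat <- fitExpDecay(CorrelationCurve(t, rep(0.5, length(t))))
  expect_false(isConverged(flat))
})

test_that("intensity slope estimates the channel ratio", {
  set.seed(7)
  a <- matrix(runif(400, 10, 100), 20)
  fit <- intensitySlope(a, 0.7 * a, background = "none")
  expect_equal(fitParams(fit)[["k"]], 0.7, tolerance = 1e-12)
  expect_equal(fitParams(fit)[["d"]], 0, tolerance = 1e-9)

  mov <- simulateFilamentMovie(filamentMovieConfig(channel2Coupling = 0.7,
                                                   noiseGain = 0,
                                                   readNoiseSd = 0,
                                                   nFrames = 2, seed = 13))
  fit2 <- intensitySlope(frames(mov$channel1)[, , 1],
                         frames(mov$channel2)[, , 1])
  expect_equal(fitParams(fit2)[["k"]], 0.7, tolerance = 0.02)
  expect_error(intensitySlope(matrix(1, 5, 5), matrix(runif(25), 5),
                              background = "none"), "zero variance")
})

test_that("recruitment-rate fit recovers the rate and preserves ordering", {
  t <- seq(0, 200, by = 5)
  y <- 0.5 * (1 - exp(-0.05 * t)) + 0.2
  fit <- recruitmentRate(data.frame(t_s = t, value = y))
  expect_true(isConverged(fit))
  expect_equal(fitParams(fit)[["a"]], 0.5, tolerance = 1e-6)
  expect_equal(fitParams(fit)[["b"]], 0.05, tolerance = 1e-6)
  expect_equal(fitParams(fit)[["c"]], 0.2, tolerance = 1e-6)

  flat <- recruitmentRate(data.frame(t_s = t, value = rep(0.4, length(t))))
  expect_false(isConverged(flat))

  set.seed(17)
  bs <- vapply(c(0.05, 0.02), function(b) {
    yy <- 0.5 * (1 - exp(-b * t)) + 0.2 + rnorm(length(t), 0, 0.05 * 0.5)
    fitParams(recruitmentRate(data.frame(t_s = t, value = yy)))[["b"]]
  }, numeric(1))
  expect_gt(bs[1], bs[2])
})
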