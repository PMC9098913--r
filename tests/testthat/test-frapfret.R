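# FRET efficiency estimators and FRAP profile decomposition.

mkTrace <- function(donorPre, donorPost, nPre = 5, nPost = 5,
                    accPre = 200, accPost = 5) {
  FretTrace(times = seq_len(nPre + nPost) - 1,
            donor = c(rep(donorPre, nPre), rep(donorPost, nPost)),
            acceptor = c(rep(accPre, nPre), rep(accPost, nPost)),
            bleachFrame = nPre + 1L)
}

test_that("acceptor-photobleaching FRET efficiency follows the donor gain", {
  expect_equal(fretEfficiencyAP(mkTrace(80, 100))$e_percent, 20)
  expect_equal(fretEfficiencyAP(mkTrace(100, 100))$e_percent, 0)
  # literal ratio reading gives 50% for an unchanged donor
  expect_equal(fretEfficiencyAP(mkTrace(100, 100), literal = TRUE)$e_percent,
               50)
  # unbleached acceptor is refused
  expect_error(fretEfficiencyAP(mkTrace(80, 100, accPost = 150)),
               "not bleached")
  # generator round trip with noise
  tr <- simulateFretTrace(0.25, donorPreLevel = 500, bleachFrame = 11,
                          nFrames = 30, noiseSd = 0.01, seed = 3)
  expect_lt(abs(fretEfficiencyAP(tr)$e_percent - 25), 1)
})

test_that("spectral FRET efficiency is the peak proximity ratio", {
  wl <- 550:700
  spec <- data.frame(wavelength = wl, intensity = 1)
  spec$intensity[wl == 565] <- 300
  spec$intensity[wl == 670] <- 100
  expect_equal(fretEfficiencySpectral(spec), 100 * 100 / 400)
  spec$intensity[wl == 670] <- 300
  expect_equal(fretEfficiencySpectral(spec), 50)
  spec$intensity[wl == 670] <- 0
  expect_equal(fretEfficiencySpectral(spec), 0)
  expect_error(fretEfficiencySpectral(
    data.frame(wavelength = 550:600, intensity = 1)), "cover")
})

test_that("recovery-profile extraction round-trips the generator", {
  # uniform movie: flat profile at 1
  uni <- ImageSeries(array(7, c(20, 40, 6)), pixelSize = 0.5,
                     frameInterval = 1)
  # force an artificial bleach frame so the drop detector is bypassed
  uniP <- extractRecoveryProfile(uni, c(10, 5, 10, 10), bleachFrame = 3)
  expect_true(all(abs(uniP@intensities - 1) < 1e-12))

  # render generator output into frames and extract it back
  px <- 0.25
  nxpix <- 80
  times <- (1:10 - 0.5) * 1
  prof <- simulateFrapProfiles(dCoeff = 0.1, kOff = 0.05, domainLength = 20,
                               bleachWindow = c(8, 12), bleachDepth = 0.8,
                               times = times, noiseSd = 0, seed = 1,
                               nx = nxpix)
  f <- array(0, c(16, nxpix, 12))
  f[, , 1:2] <- 100
  for (j in 1:10) f[, , j + 2] <- matrix(100 * prof@intensities[, j],
                                         16, nxpix, byrow = TRUE)
  ser <- ImageSeries(f, pixelSize = px, frameInterval = 1)
  ext <- extractRecoveryProfile(ser, c(32, 4, 16, 8))
  expect_equal(ext@times, times)
  rms <- sqrt(mean((ext@intensities - prof@intensities)^2))
  expect_lt(rms, 0.02)
  expect_equal(ext@bleachWindow, c(8, 12))

  # mirroring leaves a symmetric profile unchanged
  extM <- extractRecoveryProfile(ser, c(32, 4, 16, 8), mirror = TRUE)
  expect_equal(extM@intensities, ext@intensities, tolerance = 1e-6)

  expect_error(extractRecoveryProfile(ser, c(70, 0, 20, 8)), "bounds")
})

test_that("forward model conserves mass and matches the exchange limit", {
  times <- seq(0.5, 30, by = 0.5)
  # k = 0: spatial integral of the bleach deficit is constant
  prof <- simulateFrapProfiles(0.15, 0, 20, c(8, 12), 0.9, times,
                               noiseSd = 0, seed = 1)
  deficit <- colSums(1 - prof@intensities)
  expect_lt(max(abs(deficit - deficit[1])) / deficit[1], 1e-6)

  # D = 0: every position relaxes exponentially; the fitted k_off matches
  # the per-position rate to < 1%
  profE <- simulateFrapProfiles(0, 0.37, 20, c(8, 12), 0.9,
                                (1:12 - 0.5) * 0.5, noiseSd = 0, seed = 1)
  fitE <- fitFrap(profE)
  expect_lt(abs(fitParams(fitE)[["k_off"]] - 0.37) / 0.37, 0.01)
  expect_lt(fitParams(fitE)[["D"]], 0.003)
})

test_that("free diffusion spreads a narrow bleach as the heat kernel", {
  # narrow Gaussian bleach far from the boundaries, no exchange
  L <- 40; nx <- 400
  dx <- L / nx
  xs <- (seq_len(nx) - 0.5) * dx
  sigma0 <- 1
  init <- 1 - 0.8 * exp(-(xs - 20)^2 / (2 * sigma0^2))
  times <- seq(0, 8, by = 1)
  D <- 0.5
  out <- SLBdynamics:::frapForwardModel(D, 0, xs, times, init, nSub = 20)
  for (j in seq_along(times)) {
    w <- 1 - out[, j]
    w <- w / sum(w)
    v <- sum(w * xs^2) - sum(w * xs)^2
    expect_lt(abs(v - (sigma0^2 + 2 * D * times[j])) /
                (sigma0^2 + 2 * D * times[j]), 0.05)
  }
})

test_that("FRAP fit separates diffusion from exchange at 2% noise", {
  times <- (1:15 - 0.5) * 2
  prof <- simulateFrapProfiles(0.14, 0.04, 20, c(7, 13), 0.9, times,
                               noiseSd = 0.02, seed = 7)
  fit <- fitFrap(prof)
  p <- fitParams(fit)
  expect_lt(abs(p[["D"]] - 0.14) / 0.14, 0.15)
  expect_lt(abs(p[["k_off"]] - 0.04) / 0.04, 0.15)

  flat <- RecoveryProfile(positions = (1:40 - 0.5) * 0.5,
                          times = (1:6 - 0.5),
                          intensities = matrix(1, 40, 6),
                          bleachWindow = c(8, 12))
  expect_error(fitFrap(flat), "not bleached")
})

test_that("pure-exchange profiles leave the fitted D indistinguishable from zero", {
  times <- (1:12 - 0.5) * 1
  prof <- simulateFrapProfiles(0, 0.1, 20, c(8, 12), 0.85, times,
                               noiseSd = 0.01, seed = 11)
  fit <- fitFrap(prof)
  D <- fitParams(fit)[["D"]]
  se <- fitStderr(fit)[["D"]]
  ciIncludesZero <- if (is.finite(se)) D - 1.96 * se <= 0 else D < 1e-4
  expect_true(ciIncludesZero || D < 1e-3)
})
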