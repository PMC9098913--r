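# Dwell-time rates, photobleach-corrected lifetimes and MSD diffusion.

test_that("apparent off-rate MLE recovers simulated rates", {
  set.seed(41)
  tl <- 0.25
  dur <- ceiling(rexp(1e4, 0.25) / tl) * tl        # mean 4 s dwells
  fit <- apparentOffRate(DwellDataset(tl, 0.05, dur))
  expect_lt(abs(fitParams(fit)[["k_eff"]] - 0.25), 0.01)

  # long-lifetime fixture: inverse relation at the 19.4 s dwell scale
  dur2 <- ceiling(rexp(2e4, 1 / 19.4) / 0.1) * 0.1
  fit2 <- apparentOffRate(DwellDataset(0.1, 0.05, dur2))
  expect_equal(fitParams(fit2)[["k_eff"]], 1 / 19.4, tolerance = 0.03)

  expect_error(apparentOffRate(DwellDataset(1, 0.05, rep(1, 5))),
               "at least 20")
  oneFrame <- apparentOffRate(DwellDataset(1, 0.05, rep(1, 50)))
  expect_false(isConverged(oneFrame))
})

test_that("lifetime regression is exact on closed-form inputs", {
  tl <- c(0.125, 0.25, 0.5, 1, 2)
  kEff <- 0.05 + 0.2 / tl
  fit <- lifetimeFromRates(kEff, tl)
  p <- fitParams(fit)
  expect_equal(p[["k_off"]], 0.05, tolerance = 1e-12)
  expect_equal(p[["lifetime"]], 20, tolerance = 1e-9)
  expect_equal(p[["bleach_number"]], 0.2, tolerance = 1e-12)

  # estimate is invariant to which >= 3 intervals are used
  for (idx in list(1:3, 2:4, c(1, 3, 5), 2:5)) {
    expect_equal(
      fitParams(lifetimeFromRates(kEff[idx], tl[idx]))[["lifetime"]], 20,
      tolerance = 1e-9)
  }
  expect_error(lifetimeFromRates(kEff[1:2], tl[1:2]), "3 distinct")
  # k_eff * tau_tl decreasing in tau_tl: bleaching-dominated, flagged
  neg <- lifetimeFromRates(0.3 / tl - 0.1, tl)
  expect_false(isConverged(neg))
})

test_that("bleach-corrected lifetime recovers the truth within 10%", {
  for (cfg in list(c(kOff = 0.04, bn = 0.1, seed = 51),
                   c(kOff = 0.04, bn = 0.3, seed = 52),
                   c(kOff = 0.37, bn = 0.1, seed = 53),
                   c(kOff = 0.37, bn = 0.3, seed = 54))) {
    sets <- simulateDwellTracks(dwellSimConfig(
      kOffTrue = cfg[["kOff"]], bleachRate = cfg[["bn"]] / 0.05,
      integrationTime = 0.05, nMoleculesPerInterval = 10000,
      seed = cfg[["seed"]]))
    fit <- bleachCorrectedLifetime(sets)
    p <- fitParams(fit)
    expect_lt(abs(p[["k_off"]] - cfg[["kOff"]]) / cfg[["kOff"]], 0.1)
    expect_lt(abs(p[["k_off"]] - cfg[["kOff"]]),
              3 * fitStderr(fit)[["k_off"]] + 1e-9)
    expect_lt(abs(p[["lifetime"]] - 1 / cfg[["kOff"]]) / (1 / cfg[["kOff"]]),
              0.1)
  }
  # no bleaching: intercept near zero
  sets0 <- simulateDwellTracks(dwellSimConfig(kOffTrue = 0.1,
                                              bleachRate = 0,
                                              nMoleculesPerInterval = 10000,
                                              seed = 55))
  expect_lt(abs(fitParams(bleachCorrectedLifetime(sets0))[["bleach_number"]]),
            0.02)
})

test_that("MSD diffusion estimation handles the canonical cases", {
  still <- data.frame(track_id = "s", frame = 0:20, t_s = (0:20) * 0.1,
                      x_um = 1, y_um = 2)
  fit <- msdDiffusion(still)
  expect_equal(fitParams(fit)[["D"]], 0)

  set.seed(61)
  td <- randomTrack(1000, D = 0.14, dt = 0.1)
  # short-lag fit: long lags of a time-averaged MSD are strongly
  # correlated, so a 10-lag fit is the reliable estimator for long tracks
  fitB <- msdDiffusion(td, maxLagFraction = 0.01)
  expect_lt(abs(fitParams(fitB)[["D"]] - 0.14) / 0.14, 0.15)

  short <- randomTrack(4, dt = 0.1)                   # 0.3 s
  sk <- msdDiffusion(short, minTrackDuration = 0.4)
  expect_false(isConverged(sk))
  expect_match(sk@diagnostics$reason, "below")
})

test_that("ensemble median per-track D is accurate for 50-step tracks", {
  sim <- simulateTwoStateTracks(twoStateSimConfig(
    nMolecules = 150, nFrames = 51, kBind = 0, dFree = 0.2,
    localizationNoiseSd = 0.02, fovSize = 50, seed = 71))
  d <- trackData(sim$tracks)
  Ds <- vapply(split(d, d$track_id),
               function(td) fitParams(msdDiffusion(td))[["D"]], numeric(1))
  expect_lt(abs(median(Ds) - 0.2) / 0.2, 0.1)
})
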