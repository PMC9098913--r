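# Synthetic-data generators: determinism, statistical structure, and the
# closed-form relations their ground truth must obey.

test_that("two-state simulator is reproducible and rejects bad configs", {
  cfg <- twoStateSimConfig(nMolecules = 5, nFrames = 60, seed = 9)
  a <- simulateTwoStateTracks(cfg)
  b <- simulateTwoStateTracks(cfg)
  expect_identical(trackData(a$tracks), trackData(b$tracks))
  expect_identical(a$truth, b$truth)

  expect_error(twoStateSimConfig(dFree = -1), "dFree")
  expect_error(twoStateSimConfig(dTrapped = 0.5, dFree = 0.2), "dTrapped")
  expect_error(twoStateSimConfig(crossingProbability = 1.5),
               "crossingProbability")
  expect_error(twoStateSimConfig(fovSize = 0), "fovSize")
})

test_that("without trapping, displacements are pure free diffusion", {
  cfg <- twoStateSimConfig(nMolecules = 30, nFrames = 400, kBind = 0,
                           dTrapped = 0.2, localizationNoiseSd = 0,
                           fovSize = 50, seed = 3)
  sim <- simulateTwoStateTracks(cfg)
  expect_identical(nrow(sim$truth), 0L)
  d <- trackData(sim$tracks)
  steps <- unlist(lapply(split(d, d$track_id),
                         function(td) c(diff(td$x_um), diff(td$y_um))))
  expect_gt(length(steps), 2e4)
  expect_lt(abs(var(steps) / (2 * 0.2 * 0.051) - 1), 0.05)
})

test_that("ground-truth trapping durations are exponential with mean 1/k_unbind", {
  # fine time discretization so the geometric frame count approximates the
  # continuous exponential the KS test checks against
  cfg <- twoStateSimConfig(nMolecules = 140, nFrames = 3000, kBind = 2,
                           kUnbind = 1.5, frameInterval = 0.01, seed = 5)
  sim <- simulateTwoStateTracks(cfg)
  dur <- sim$truth$duration[!sim$truth$censored]
  expect_gt(length(dur), 1000)
  expect_lt(abs(mean(dur) - 1 / 1.5), 3 * sd(dur) / sqrt(length(dur)))
  ks <- suppressWarnings(ks.test(dur, "pexp", 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("trapped molecules stay tethered to their zone", {
  cfg <- twoStateSimConfig(nMolecules = 50, nFrames = 400, kBind = 0.5,
                           kUnbind = 0.5, localizationNoiseSd = 0, seed = 12)
  sim <- simulateTwoStateTracks(cfg)
  tru <- sim$truth[!sim$truth$censored, ]
  expect_gt(nrow(tru), 20)
  d <- trackData(sim$tracks)
  # every position during a trapped interval lies within the zone radius
  # (25 nm) of the event centroid
  spread <- vapply(seq_len(nrow(tru)), function(k) {
    td <- d[d$track_id == tru$track_id[k] &
            d$t_s >= tru$start_time[k] & d$t_s <= tru$end_time[k], ]
    max(sqrt((td$x_um - mean(td$x_um))^2 + (td$y_um - mean(td$y_um))^2))
  }, numeric(1))
  expect_lt(median(spread), 0.06)
})

test_that("dwell simulator obeys the closed-form apparent rate", {
  # no bleaching: mean observed dwell ~ 1/k_off at every interval
  sets <- simulateDwellTracks(dwellSimConfig(kOffTrue = 0.05, bleachRate = 0,
                                             nMoleculesPerInterval = 5000,
                                             seed = 2))
  for (d in sets) {
    m <- mean(d@durations)
    expect_lt(abs(m - 1 / 0.05) / (1 / 0.05), 0.1)
  }

  # bleaching: apparent rate at tau_tl = 1 s is k_off + k_b tau_int / tau_tl
  cfg <- dwellSimConfig(kOffTrue = 0.05, bleachRate = 4,
                        integrationTime = 0.05,
                        nMoleculesPerInterval = 10000, seed = 4)
  sets <- simulateDwellTracks(cfg)
  fit <- apparentOffRate(sets[["1"]])
  expect_lt(abs(fitParams(fit)[["k_eff"]] - 0.25),
            3 * fitStderr(fit)[["k_eff"]])

  # MLE recovery without bleaching, within 3 standard errors
  sets0 <- simulateDwellTracks(dwellSimConfig(kOffTrue = 0.05,
                                              bleachRate = 0,
                                              lapseIntervals = 0.5,
                                              nMoleculesPerInterval = 10000,
                                              seed = 6))
  fit0 <- apparentOffRate(sets0[[1]])
  expect_lt(abs(fitParams(fit0)[["k_eff"]] - 0.05),
            3 * fitStderr(fit0)[["k_eff"]])

  # vacuous case
  empty <- simulateDwellTracks(dwellSimConfig(nMoleculesPerInterval = 0))
  expect_identical(length(empty[[1]]@durations), 0L)
  expect_error(dwellSimConfig(lapseIntervals = numeric(0)), "empty")
})

test_that("filament movie couples channel 2 to channel 1 as configured", {
  # full coupling, no noise: channels identical up to global scaling
  mov <- simulateFilamentMovie(filamentMovieConfig(channel2Coupling = 1,
                                                   noiseGain = 0,
                                                   readNoiseSd = 0,
                                                   nFrames = 3, seed = 8))
  for (i in 1:3) {
    expect_equal(pearsonCC(frames(mov$channel1)[, , i],
                           frames(mov$channel2)[, , i]), 1, tolerance = 1e-6)
  }

  # zero coupling: channel 2 is homogeneous background + noise, so the
  # correlation with the filament channel vanishes
  mov0 <- simulateFilamentMovie(filamentMovieConfig(channel2Coupling = 0,
                                                    readNoiseSd = 0.05,
                                                    nFrames = 3, seed = 8))
  r <- vapply(1:3, function(i) pearsonCC(frames(mov0$channel1)[, , i],
                                         frames(mov0$channel2)[, , i]),
              numeric(1))
  expect_lt(max(abs(r)), 0.15)

  # no treadmilling: differential frames carry only noise
  movS <- simulateFilamentMovie(filamentMovieConfig(treadmillSpeed = 0,
                                                    noiseGain = 0,
                                                    readNoiseSd = 0,
                                                    nFrames = 4, seed = 8))
  expect_equal(max(frames(differentialSeries(movS$channel1))), 0)

  expect_error(filamentMovieConfig(nFrames = 1), "2 frames")
  # determinism
  m1 <- simulateFilamentMovie(filamentMovieConfig(nFrames = 2, seed = 3))
  m2 <- simulateFilamentMovie(filamentMovieConfig(nFrames = 2, seed = 3))
  expect_identical(frames(m1$channel1), frames(m2$channel1))
})

test_that("FRAP profile generator honours its analytic limits", {
  times <- seq(0.5, 20, by = 0.5)
  # pure exchange: every position recovers as 1 - depth * exp(-k t)
  prof <- simulateFrapProfiles(dCoeff = 0, kOff = 0.1, domainLength = 20,
                               bleachWindow = c(8, 12), bleachDepth = 0.8,
                               times = times, noiseSd = 0, seed = 1)
  inWin <- prof@positions >= 8 & prof@positions <= 12
  expected <- 1 - 0.8 * exp(-0.1 * times)
  for (j in c(1, 10, 40)) {
    expect_equal(unname(prof@intensities[inWin, j][3]), expected[j],
                 tolerance = 1e-4)
  }
  # no exchange: reflecting boundaries conserve total fluorescence
  prof2 <- simulateFrapProfiles(dCoeff = 0.2, kOff = 0, domainLength = 20,
                                bleachWindow = c(8, 12), bleachDepth = 0.8,
                                times = times, noiseSd = 0, seed = 1)
  m <- colMeans(prof2@intensities)
  expect_lt(max(abs(m - m[1])) / m[1], 1e-6)
  expect_error(simulateFrapProfiles(0.1, 0.1, -1, c(0, 1), 0.5, 1), "domain")
})

test_that("FRET trace and binding curve generators match their formulas", {
  # E = 0: flat donor
  tr0 <- simulateFretTrace(0, donorPreLevel = 80, bleachFrame = 5,
                           nFrames = 10)
  expect_equal(unique(tr0@donor), 80)
  # donor gain: pre / (1 - E)
  tr <- simulateFretTrace(0.2, donorPreLevel = 80, bleachFrame = 5,
                          nFrames = 10)
  expect_equal(tr@donor[10], 100)
  expect_equal(tr@donor[4], 80)
  expect_error(simulateFretTrace(1, 80, 5, 10), "eTrue")

  # half-maximal response at c = k for a Langmuir (n = 1) isotherm
  bs <- simulateBindingCurve("hill_qcmd",
                             list(S = 0, E = -30, n = 1, k = 0.21),
                             concentrations = c(0.05, 0.21, 3))
  expect_equal(bs@responses[2], -15, tolerance = 1e-12)
})
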