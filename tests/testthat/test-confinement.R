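# Packing-coefficient computation and confinement-event calling.

test_that("packing coefficient matches the hand-computed square path", {
  sq <- TrackSet(data.frame(track_id = "sq", frame = 0:4,
                            x_um = c(0, 0.1, 0.1, 0, 0),
                            y_um = c(0, 0, 0.1, 0.1, 0)),
                 frameInterval = 0.05)
  prof <- packingCoefficient(sq, windowN = 4)[[1]]
  # four steps of 0.1 um: sum sq = 0.04 um^2; hull = 0.1 x 0.1 square
  expect_equal(prof@p, 0.04 / 0.01^2)
  expect_identical(length(prof@p), 1L)
})

test_that("degenerate hulls and rescaling behave as the formula dictates", {
  lin <- TrackSet(data.frame(track_id = "l", frame = 0:4,
                             x_um = seq(0, 0.4, by = 0.1),
                             y_um = seq(0, 0.8, by = 0.2)),
                  frameInterval = 0.05)
  expect_identical(packingCoefficient(lin, windowN = 4)[[1]]@p, Inf)

  set.seed(23)
  td <- randomTrack(40)
  p1 <- packingCoefficient(TrackSet(td, 0.05), windowN = 5)[[1]]@p
  td2 <- td; td2$x_um <- 2 * td2$x_um; td2$y_um <- 2 * td2$y_um
  p2 <- packingCoefficient(TrackSet(td2, 0.05), windowN = 5)[[1]]@p
  expect_equal(p2, p1 / 4, tolerance = 1e-12)

  expect_error(packingCoefficient(TrackSet(td, 0.05), windowN = 2),
               "at least 3")
})

test_that("packing coefficient equals the brute-force oracle", {
  set.seed(29)
  for (i in 1:100) {
    td <- randomTrack(sample(12:40, 1), D = runif(1, 0.01, 0.3))
    n <- sample(3:8, 1)
    if (nrow(td) <= n + 1) next
    p <- packingCoefficient(TrackSet(td, 0.05), windowN = n)[[1]]@p
    o <- packingOracle(td, n)
    fin <- is.finite(p) & is.finite(o)
    expect_equal(p[fin], o[fin], tolerance = 1e-10)
    expect_identical(is.infinite(p), is.infinite(o))
  }
})

test_that("frame gaps invalidate windows that span them", {
  td <- randomTrack(20)
  td <- td[td$frame != 10L, ]
  prof <- packingCoefficient(TrackSet(td, 0.05), windowN = 4)[[1]]
  gapIdx <- which(is.na(prof@p))
  expect_gt(length(gapIdx), 0)
  # exactly the windows whose point range includes the missing frame
  expect_true(all(prof@times[gapIdx] > (10 - 5) * 0.05 - 1e-9))
  expect_true(all(prof@times[gapIdx] < 10 * 0.05 + 1e-9))
})

test_that("duration threshold converts to the documented frame counts", {
  expect_identical(tThreshToFrames(0.25, 0.051), 5L)
  expect_identical(tThreshToFrames(0.25, 0.032), 8L)
})

test_that("event calling respects thresholds, runs and extents", {
  mkProf <- function(p, dt = 0.051, n = 5L) {
    new("PackingProfile", trackId = "t", times = (seq_along(p) - 1) * dt,
        p = p, windowN = n, frameInterval = dt)
  }
  # everywhere below threshold: no events
  expect_identical(nrow(detectConfinement(mkProf(rep(10, 50)))), 0L)
  # a 4-window run is below the 5-frame minimum at 51 ms
  p <- rep(10, 30); p[10:13] <- 5000
  expect_identical(nrow(detectConfinement(mkProf(p))), 0L)
  # a 6-window run is an event spanning windows + coverage
  p <- rep(10, 30); p[10:15] <- 5000
  ev <- detectConfinement(mkProf(p))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$start_time, 9 * 0.051)
  expect_equal(ev$end_time, (14 + 5) * 0.051)
  expect_equal(ev$duration, (14 + 5 - 9) * 0.051)
  expect_gte(ev$duration, 0.25)
  # Inf windows count as confined; NA breaks runs
  p <- rep(10, 30); p[10:15] <- Inf
  expect_identical(nrow(detectConfinement(mkProf(p))), 1L)
  p <- rep(10, 30); p[10:15] <- 5000; p[12] <- NA
  expect_identical(nrow(detectConfinement(mkProf(p))), 0L)
})

test_that("track filtering removes short and stationary tracks", {
  dt <- 0.1
  short <- randomTrack(6, dt = dt, id = "short")       # 0.5 s
  long <- randomTrack(30, dt = dt, id = "long")        # 2.9 s
  still <- long; still$track_id <- "still"
  still$x_um <- still$x_um[1]; still$y_um <- still$y_um[1]
  ts <- TrackSet(rbind(short, long, still), dt)
  expect_setequal(trackIds(filterTracks(ts)), c("long", "still"))
  expect_setequal(trackIds(filterTracks(ts, minDuration = 0,
                                        minNetDisplacement = 0)),
                  c("short", "long", "still"))
  expect_false("still" %in%
    trackIds(filterTracks(ts, minNetDisplacement = 0.05)))
})

test_that("confinement statistics recover an exponential mean duration", {
  set.seed(31)
  dur <- ceiling(rexp(1000, 1 / 0.35) / 0.051) * 0.051
  events <- data.frame(track_id = paste0("t", 1:1000), duration = dur)
  tracks <- TrackSet(do.call(rbind, lapply(paste0("t", 1:1000), function(id)
    data.frame(track_id = id, frame = 0:1, x_um = c(0, 0.1),
               y_um = c(0, 0)))), 0.051)
  st <- confinementStats(events, tracks)
  expect_lt(abs(st$tau - 0.35), 0.05)
  expect_equal(st$confinedFraction, 100)

  one <- confinementStats(events[1, ], tracks)
  expect_true(is.na(one$tau))
  expect_equal(one$confinedFraction, 0.1)
})

test_that("validation metrics are exact for perfect detection", {
  truth <- data.frame(track_id = c("a", "a", "b"),
                      start_time = c(1, 5, 2), end_time = c(2, 6.5, 4),
                      duration = c(1, 1.5, 2), zone_id = "z",
                      censored = FALSE)
  det <- truth[, c("track_id", "start_time", "end_time", "duration")]
  v <- validateAgainstTruth(det, truth, frameInterval = 0.051, tThresh = 0.5)
  expect_equal(v$durationError, 0)
  expect_equal(v$recall, 1)
  expect_equal(v$precision, 1)
  bad <- det; bad$track_id <- "zzz"
  expect_error(validateAgainstTruth(bad, truth, frameInterval = 0.051),
               "track ids")
})

test_that("pure Brownian motion rarely triggers false confinement", {
  sim <- simulateTwoStateTracks(twoStateSimConfig(nMolecules = 100,
                                                  kBind = 0, seed = 37))
  ev <- confinementAnalysis(sim$tracks)
  falseRate <- length(unique(ev$track_id)) / 100
  expect_lt(falseRate, 0.05)
})

test_that("per-event duration error grows with trapped-state mobility", {
  errs <- vapply(c(0.002, 0.005, 0.008), function(dT) {
    det <- list(); tru <- list()
    for (s in 1:2) {
      sim <- simulateTwoStateTracks(twoStateSimConfig(dTrapped = dT,
                                                      seed = 300 + s))
      det[[s]] <- confinementAnalysis(sim$tracks)
      tru[[s]] <- sim$truth
    }
    validateAgainstTruth(do.call(rbind, det), do.call(rbind, tru),
                         frameInterval = 0.051)$perPairMAE
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})
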