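# Independent oracles used across the suite.

# Convex hull by Andrew's monotone chain (independent of grDevices::chull),
# returning the polygon area by the shoelace formula.
hullAreaOracle <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  m <- length(hx)
  abs(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)) / 2
}

# Direct loop evaluation of the packing coefficient for one track table.
packingOracle <- function(td, windowN) {
  m <- nrow(td)
  nW <- m - windowN
  p <- rep(NA_real_, max(nW, 0))
  for (i in seq_len(nW)) {
    idx <- i:(i + windowN)
    if (any(diff(td$frame[idx]) != 1L)) next
    sumsq <- 0
    for (j in i:(i + windowN - 1L)) {
      sumsq <- sumsq + (td$x_um[j + 1] - td$x_um[j])^2 +
        (td$y_um[j + 1] - td$y_um[j])^2
    }
    area <- hullAreaOracle(td$x_um[idx], td$y_um[idx])
    p[i] <- if (area < 1e-12) Inf else sumsq / area^2
  }
  p
}

# Random Brownian-ish track table for property tests.
randomTrack <- function(nPoints, D = 0.1, dt = 0.05, id = "t") {
  data.frame(track_id = id, frame = 0:(nPoints - 1L),
             t_s = (0:(nPoints - 1L)) * dt,
             x_um = cumsum(c(runif(1, 0, 5), rnorm(nPoints - 1L, 0,
                                                   sqrt(2 * D * dt)))),
             y_um = cumsum(c(runif(1, 0, 5), rnorm(nPoints - 1L, 0,
                                                   sqrt(2 * D * dt)))))
}
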