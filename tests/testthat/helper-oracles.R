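# Independent oracles kept deliberately separate from the package code
# paths they check.

# Natural cubic spline by direct tridiagonal solve for the second
# derivatives; returns an evaluator function.
naturalSplineOracle <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  M <- rep(0, n)
  if (n > 2) {
    m <- n - 2
    A <- matrix(0, m, m)
    rhs <- numeric(m)
    for (i in seq_len(m)) {
      A[i, i] <- (h[i] + h[i + 1]) / 3
      if (i > 1) A[i, i - 1] <- h[i] / 6
      if (i < m) A[i, i + 1] <- h[i + 1] / 6
      rhs[i] <- (y[i + 2] - y[i + 1]) / h[i + 1] - (y[i + 1] - y[i]) / h[i]
    }
    M[2:(n - 1)] <- solve(A, rhs)
  }
  function(t) {
    vapply(t, function(tt) {
      i <- findInterval(tt, x, all.inside = TRUE)
      hh <- h[i]
      a <- (x[i + 1] - tt) / hh
      b <- (tt - x[i]) / hh
      a * y[i] + b * y[i + 1] +
        ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * hh^2 / 6
    }, 0)
  }
}

# Unsigned angle between unit vectors via arccos of the dot product.
acosAngleOracle <- function(u, v) {
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Brute-force stripe lateral MIP: mask voxels by the stripe condition on
# their y-centers, then take the max over y for each (x, z).
stripeOracle <- function(arr, h, midlineY, widthMm) {
  nx <- dim(arr)[1]; ny <- dim(arr)[2]; nz <- dim(arr)[3]
  yc <- (seq_len(ny) - 0.5) * h
  out <- matrix(0, nx, nz)
  for (i in seq_len(nx)) {
    for (k in seq_len(nz)) {
      best <- -Inf
      for (j in seq_len(ny)) {
        if (abs(yc[j] - midlineY[i]) <= widthMm / 2 && arr[i, j, k] > best)
          best <- arr[i, j, k]
      }
      out[i, k] <- if (is.finite(best)) best else 0
    }
  }
  out
}

# Exhaustive grid over roll/yaw: the minimum achievable sum of squared y.
poseGridOracle <- function(p, degRange = 20, degStep = 0.05) {
  angs <- seq(-degRange, degRange, by = degStep) * pi / 180
  best <- Inf
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  for (r in angs) {
    y1 <- y * cos(r) - z * sin(r)
    Sxx <- sum(x^2); Sxy <- sum(x * y1); Syy <- sum(y1^2)
    # yaw t: y2 = x sin(t) + y1 cos(t)
    f <- sin(angs)^2 * Sxx + 2 * sin(angs) * cos(angs) * Sxy +
      cos(angs)^2 * Syy
    best <- min(best, min(f))
  }
  best
}

# General rigid motion applied directly to trajectory points (the package
# API deliberately exposes only roll/yaw poses).
rigidTransform <- function(traj, R, t = c(0, 0, 0)) {
  traj@points <- sweep(traj@points %*% t(R), 2, t, "+")
  traj
}

randomRotation <- function() {
  a <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]),
                 0, sin(a[1]), cos(a[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0,
                 -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

randomUnitVectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# A small smooth labeled trajectory for unit tests.
testTrajectory <- function(n = 12, spacing = 2.5, amp = 3, seed = NULL,
                           jitter = 0, subject = list()) {
  sp <- phantomSpec(nVertebrae = n, spacingMm = spacing,
                    sagittalProfile = list(
                      type = "gaussians",
                      bumps = data.frame(amplitude = amp,
                                         center = (n - 1) * spacing / 2,
                                         width = (n - 1) * spacing / 4)),
                    jitterSdMm = jitter, seed = if (is.null(seed)) 1 else seed,
                    anchorIndex = ceiling(n / 2))
  makePhantomTrajectory(sp, subject = subject)
}
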