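test_that("phantom generation is deterministic in its seed", {
  sp <- phantomSpec(seed = 42)
  a <- makePhantomTrajectory(sp)
  b <- makePhantomTrajectory(sp)
  expect_identical(refPoints(a$trajectory), refPoints(b$trajectory))
  expect_identical(a$truth@trueCurvature, b$truth@trueCurvature)
  c <- makePhantomTrajectory(phantomSpec(seed = 43))
  expect_false(identical(refPoints(a$trajectory), refPoints(c$trajectory)))
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(makePhantomTrajectory(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a flat, noise-free spec yields a straight trajectory with zero truth", {
  sp <- phantomSpec(sagittalProfile = list(), jitterSdMm = 0)
  ph <- makePhantomTrajectory(sp)
  p <- refPoints(ph$trajectory)
  expect_true(all(p[, c("y", "z")] == 0))
  expect_equal(unname(diff(p[, "x"])), rep(2.5, 25), tolerance = 1e-9)
  expect_true(all(abs(ph$truth@trueCurvature$angle_deg) < 1e-9))
  expect_identical(vertebraLabels(ph$trajectory)[11], "L6")
})

test_that("equal-arc sampling holds on curved profiles and exact arcs", {
  ph <- makePhantomTrajectory(phantomSpec(jitterSdMm = 0))
  seg <- sqrt(rowSums(diff(refPoints(ph$trajectory))^2))
  # chord length is slightly below arc length but uniform
  expect_lt(max(abs(seg - 2.5)) / 2.5, 0.01)

  arc <- makePhantomTrajectory(
    phantomSpec(nVertebrae = 12, spacingMm = 2,
                sagittalProfile = list(type = "arc", radius = 20),
                jitterSdMm = 0, anchorIndex = 6))
  expect_equal(max(abs(arc$truth@trueCurvature$angle_deg -
                         2 * 2 / 20 * 180 / pi)), 0, tolerance = 1e-9)
  expect_error(makePhantomTrajectory(
    phantomSpec(nVertebrae = 26, spacingMm = 2.5,
                sagittalProfile = list(type = "arc", radius = 10),
                anchorIndex = 11)), "180")
})

test_that("poses compose as rigid motions and invert through correction", {
  ph <- testTrajectory(seed = 12)
  traj <- ph$trajectory
  expect_equal(refPoints(applyPose(traj)), refPoints(traj))

  posed <- applyPose(traj, roll = 0.2, yaw = -0.1, dx = 2, dz = -1)
  rec <- correctPose(posed)
  expect_lt(sum(refPoints(rec$trajectory)[, "y"]^2), 1e-12)

  # successive poses equal one explicitly composed rigid motion
  p1 <- applyPose(applyPose(traj, roll = 0.1, dx = 1),
                  yaw = 0.15, dz = -0.5)
  R1 <- spinetrace:::.rotX(0.1); R2 <- spinetrace:::.rotZ(0.15)
  c0 <- colMeans(traj@points)
  q <- sweep(traj@points, 2, c0, "-") %*% t(R1)
  q <- sweep(q, 2, c0, "+"); q[, 1] <- q[, 1] + 1
  c1 <- colMeans(q)
  q <- sweep(sweep(q, 2, c1, "-") %*% t(R2), 2, c1, "+")
  q[, 3] <- q[, 3] - 0.5
  expect_equal(unname(refPoints(p1)), unname(q), tolerance = 1e-12)
})

test_that("voxelization renders separated vertebral bodies over background", {
  sp <- phantomSpec(nVertebrae = 4, sagittalProfile = list(),
                    jitterSdMm = 0, anchorIndex = 2,
                    blob = list(semiAxesMm = c(0.9, 0.6, 0.6),
                                intensity = 1000, background = 50,
                                noiseSd = 0))
  ph <- makePhantomTrajectory(sp)
  vx <- voxelizePhantom(ph$trajectory, sp)
  arr <- intensities(vx$volume)

  # zero-noise background: only two intensity levels
  expect_setequal(unique(as.vector(arr)), c(50, 1000))

  # exactly 3 supra-threshold runs along x at the blob-midpoint threshold
  runs <- rle(apply(arr, 1, max) > (1000 + 50) / 2)
  expect_equal(sum(runs$values), 3L)

  # stripe MIP along the true midline keeps gap columns below blob intensity
  tr <- vx$trajectory
  ml <- fitMidline(refPoints(tr)[, c("x", "y")])
  sm <- pixels(stripeLateralMip(vx$volume, ml, widthMm = 1))
  gapCols <- round(refPoints(tr)[, "x"] / voxelSize(vx$volume))
  expect_lt(max(sm[gapCols, ]), 1000)

  # bounding box too small is an error
  expect_error(voxelizePhantom(ph$trajectory, sp, boxMm = c(5, 5, 5)),
               "bounding box")
})

test_that("voxelization shifts the trajectory into the volume frame", {
  sp <- phantomSpec(nVertebrae = 6, jitterSdMm = 0, anchorIndex = 3)
  ph <- makePhantomTrajectory(sp)
  vx <- voxelizePhantom(ph$trajectory, sp, marginMm = 3)
  p <- refPoints(vx$trajectory)
  expect_equal(min(p[, "x"]), 3)
  expect_true(all(p >= 3 - 1e-9))
  expect_equal(unname(refPoints(ph$trajectory) +
                        matrix(vx$offsetMm, nrow(p), 3, byrow = TRUE)),
               unname(p), tolerance = 1e-12)
  # noise stream is seed-derived and reproducible
  vx2 <- voxelizePhantom(ph$trajectory, sp, marginMm = 3)
  expect_identical(intensities(vx$volume), intensities(vx2$volume))
})
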