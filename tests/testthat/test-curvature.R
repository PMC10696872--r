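test_that("vertebra axes are anterior-pointing unit chords", {
  straight <- assignIdentities(cbind(seq(0, 25, 2.5), 0, 0), "L6", 5)
  ax <- vertebraAxes(straight)
  expect_equal(nrow(ax), 10)
  expect_true(all(abs(ax$vx - 1) < 1e-12 & abs(ax$vy) < 1e-12 &
                    abs(ax$vz) < 1e-12))
  # axes are named for the vertebra posterior-flanked by the point
  expect_identical(ax$vertebra, vertebraLabels(straight)[-11])

  two <- assignIdentities(rbind(c(0, 0, 0), c(2, 0, 2)), "L5", 1)
  ax2 <- vertebraAxes(two)
  expect_equal(unlist(ax2[1, c("vx", "vy", "vz")], use.names = FALSE),
               c(sqrt(2) / 2, 0, sqrt(2) / 2))

  ph <- testTrajectory(n = 20, seed = 31, jitter = 0.1)$trajectory
  norms <- sqrt(rowSums(as.matrix(vertebraAxes(ph)[, c("vx", "vy", "vz")])^2))
  expect_true(all(abs(norms - 1) < 1e-12))

  dup <- straight
  dup@points[3, ] <- dup@points[2, ]
  expect_error(vertebraAxes(dup), vertebraLabels(straight)[2])
})

test_that("signed curvature angle follows the convexity convention", {
  expect_equal(curvatureAngle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(curvatureAngle(c(1, 0, 0), c(0, 0, 1))), 90)

  a <- 15 * pi / 180
  up <- c(cos(a), 0, sin(a)); down <- c(cos(a), 0, -sin(a))
  expect_equal(curvatureAngle(up, down), 30, tolerance = 1e-12)   # kyphotic
  expect_equal(curvatureAngle(down, up), -30, tolerance = 1e-12)  # lordotic
  expect_equal(curvatureAngle(up, down, flipSign = TRUE), -30,
               tolerance = 1e-12)

  # swapping arguments flips the sign, keeps the magnitude
  set.seed(50)
  for (i in 1:20) {
    u <- randomUnitVectors(1)[1, ]; v <- randomUnitVectors(1)[1, ]
    expect_equal(curvatureAngle(u, v), -curvatureAngle(v, u),
                 tolerance = 1e-9)
  }

  expect_error(curvatureAngle(c(1, 0, 0), c(2, 0, 0)), "unit")
})

test_that("atan2 and arcsine formulations agree for acute angles", {
  set.seed(51)
  u <- randomUnitVectors(10000)
  v <- randomUnitVectors(10000)
  flip <- rowSums(u * v) < 0
  v[flip, ] <- -v[flip, ]   # make every pair acute
  for (i in seq_len(500)) {
    cr <- c(u[i, 2] * v[i, 3] - u[i, 3] * v[i, 2],
            u[i, 3] * v[i, 1] - u[i, 1] * v[i, 3],
            u[i, 1] * v[i, 2] - u[i, 2] * v[i, 1])
    asin_deg <- asin(min(1, sqrt(sum(cr^2)))) * 180 / pi
    expect_equal(abs(curvatureAngle(u[i, ], v[i, ])), asin_deg,
                 tolerance = 1e-9)
  }
})

test_that("curvature profiles: straight is zero, circles give 2s/R", {
  straight <- assignIdentities(cbind(seq(0, 25, 2.5), 0, 0), "L6", 5)
  prof <- curvatureProfile(straight)
  expect_lt(max(abs(angles(prof))), 1e-9)
  # endpoints carry no angle: n points -> n - 3 angles
  expect_equal(length(angles(prof)), nrow(refPoints(straight)) - 3)

  arc <- makePhantomTrajectory(
    phantomSpec(nVertebrae = 12, spacingMm = 2,
                sagittalProfile = list(type = "arc", radius = 20),
                jitterSdMm = 0, anchorIndex = 6))$trajectory
  pa <- angles(curvatureProfile(arc))
  expect_equal(unname(pa), rep(2 * 2 / 20 * 180 / pi, length(pa)),
               tolerance = 1e-9)
  expect_equal(unname(pa[1]), 11.4591559, tolerance = 1e-6)

  expect_error(curvatureProfile(
    assignIdentities(cbind(c(0, 2, 4), 0, 0), "L6", 1)), ">= 4")
})

test_that("curvature is invariant under rigid motions and mirrors with z", {
  ph <- testTrajectory(n = 16, seed = 52, jitter = 0.05)
  traj <- ph$trajectory
  ref <- angles(curvatureProfile(traj))
  set.seed(53)
  for (i in 1:5) {
    moved <- rigidTransform(traj, randomRotation(), runif(3, -20, 20))
    expect_equal(abs(angles(curvatureProfile(moved))), abs(ref),
                 tolerance = 1e-9)
  }
  # pipeline transforms specifically
  expect_equal(angles(curvatureProfile(centerTrajectory(traj))), ref,
               tolerance = 1e-9)
  expect_equal(angles(curvatureProfile(correctPose(traj)$trajectory)), ref,
               tolerance = 1e-9)

  mirrored <- traj
  mirrored@points[, 3] <- -mirrored@points[, 3]
  expect_equal(angles(curvatureProfile(mirrored)), -ref, tolerance = 1e-9)
})

test_that("group profiles summarize by metadata with sample SD", {
  mk <- function(t6, subj) {
    tr <- testTrajectory(n = 10, seed = 60, subject = subj)$trajectory
    p <- curvatureProfile(tr)
    p@angles[p@vertebrae == "L5"] <- t6
    p
  }
  # single profile: mean is the profile, SD undefined
  solo <- groupProfiles(list(mk(4, list(genotype = "wt"))), "genotype")
  expect_true(all(solo$n == 1L) && all(is.na(solo$sd_deg)))

  two <- groupProfiles(list(mk(4, list(genotype = "wt")),
                            mk(-4, list(genotype = "wt"))), "genotype")
  t6 <- two[two$vertebra == "L5", ]
  expect_equal(t6$mean_deg, 0)
  expect_equal(t6$sd_deg, 4 * sqrt(2))
  expect_equal(t6$n, 2L)

  # seeded cohort vs direct recomputation, with two groups
  profs <- lapply(1:10, function(i)
    curvatureProfile(testTrajectory(n = 12, seed = 70 + i, jitter = 0.1,
                                    subject = list(genotype =
                                      if (i %% 2) "wt" else "ko"))$trajectory))
  gp <- groupProfiles(profs, "genotype")
  wt <- profs[vapply(profs, function(p) p@subject$genotype == "wt", TRUE)]
  v <- gp$vertebra[1]
  a <- vapply(wt, function(p) unname(angles(p)[v]), 0)
  row <- gp[gp$group == "wt" & gp$vertebra == v, ]
  expect_equal(row$mean_deg, mean(a))
  expect_equal(row$sd_deg, stats::sd(a))
  expect_equal(row$n, length(a))

  expect_error(groupProfiles(list()), "no profiles")
})

test_that("per-animal curvature CSV export has the hand-off columns", {
  profs <- lapply(1:2, function(i)
    curvatureProfile(testTrajectory(n = 10, seed = 80 + i,
                                    subject = list(animal = paste0("m", i))
                                    )$trajectory))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCurvatureCSV(profs, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("animal", "vertebra", "angle_deg"))
  expect_equal(nrow(df), sum(vapply(profs, function(p) length(p@angles), 0L)))
})
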