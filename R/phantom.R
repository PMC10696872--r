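#' @include trajectory.R curvature.R
NULL

#' Construct a synthetic spine specification
#'
#' Defaults generate the reference validation cohort: a 26-point
#' trajectory at 2.5 mm arc spacing covering T4..Ca6 (anchor L6 at point
#' 11), one dorsal Gaussian kyphosis bump over the thoracic band
#' (amplitude 4 mm, SD width 10 mm), a straight medio-lateral course,
#' identity pose, point jitter SD 0.1 mm and 125 um voxels.  See
#' \linkS4class{PhantomSpec} for slot semantics.
#'
#' @param nVertebrae,spacingMm,sagittalProfile,lateralProfile,pose
#'   see \linkS4class{PhantomSpec}.
#' @param jitterSdMm,seed,voxelSizeMm,anchorLabel,anchorIndex,blob
#'   see \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(nVertebrae = 26,
                        spacingMm = 2.5,
                        sagittalProfile = list(
                          type = "gaussians",
                          bumps = data.frame(amplitude = 4, center = 50,
                                             width = 10)),
                        lateralProfile = list(),
                        pose = list(roll = 0, yaw = 0, dx = 0, dz = 0),
                        jitterSdMm = 0.1,
                        seed = 1L,
                        voxelSizeMm = 0.125,
                        anchorLabel = "L6",
                        anchorIndex = 11,
                        blob = list(semiAxesMm = c(0.9, 0.6, 0.6),
                                    intensity = 1000, background = 50,
                                    noiseSd = 10)) {
  pose <- utils::modifyList(list(roll = 0, yaw = 0, dx = 0, dz = 0), pose)
  new("PhantomSpec", nVertebrae = as.integer(nVertebrae),
      spacingMm = spacingMm, sagittalProfile = sagittalProfile,
      lateralProfile = lateralProfile, pose = pose,
      jitterSdMm = jitterSdMm, seed = as.integer(seed),
      voxelSizeMm = voxelSizeMm, anchorLabel = anchorLabel,
      anchorIndex = as.integer(anchorIndex), blob = blob)
}

.gaussiansFun <- function(profile) {
  if (!length(profile)) return(function(x) rep(0, length(x)))
  b <- profile$bumps
  function(x) {
    out <- rep(0, length(x))
    for (i in seq_len(nrow(b)))
      out <- out + b$amplitude[i] *
        exp(-((x - b$center[i])^2) / (2 * b$width[i]^2))
    out
  }
}

## Equal-arc-length sampling of the phantom path.  The circular arc is
## sampled analytically (chord geometry then holds exactly); Gaussian-bump
## paths use a fine-grid cumulative arc length.
.samplePath <- function(spec) {
  n <- spec@nVertebrae
  s <- spec@spacingMm
  pr <- spec@sagittalProfile
  if (identical(pr$type, "arc")) {
    R <- pr$radius
    theta <- (n - 1) * s / R
    if (theta >= pi)
      stop("arc spans >= 180 degrees; reduce nVertebrae, spacingMm ",
           "or increase the radius")
    th <- -theta / 2 + (seq_len(n) - 1L) * s / R
    return(cbind(x = R * (sin(th) + sin(theta / 2)),
                 y = rep(0, n),
                 z = R * (cos(th) - cos(theta / 2))))
  }
  zf <- .gaussiansFun(pr)
  yf <- .gaussiansFun(spec@lateralProfile)
  target <- (n - 1) * s
  step <- 1e-3
  xg <- seq(0, target * 1.5 + 1, by = step)
  seg <- sqrt(diff(xg)^2 + diff(yf(xg))^2 + diff(zf(xg))^2)
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] < target)
    stop("internal error: path too short for requested spacing")
  xs <- stats::approx(arc, xg, xout = (seq_len(n) - 1L) * s)$y
  cbind(x = xs, y = yf(xs), z = zf(xs))
}

## Independent ground-truth curvature: arccos of the dot product of the
## neighbor axes (plus the y-sign rule), deliberately not sharing code
## with curvatureProfile()'s atan2-of-cross evaluation.
.truthCurvature <- function(traj) {
  p <- traj@points
  n <- nrow(p)
  d <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  v <- d / sqrt(rowSums(d^2))
  mid <- seq(2L, n - 2L)
  ang <- vapply(mid, function(j) {
    a <- v[j - 1L, ]; b <- v[j + 1L, ]
    mag <- acos(max(-1, min(1, sum(a * b)))) * 180 / pi
    crossY <- a[3L] * b[1L] - a[1L] * b[3L]
    if (crossY < 0) -mag else mag
  }, 0)
  data.frame(vertebra = traj@labels[mid], ordinal = traj@ordinals[mid],
             angle_deg = ang)
}

#' Generate a ground-truthed synthetic spinal trajectory
#'
#' Places reference points at equal arc-length steps along the parametric
#' phantom curve, labels them from the anchor vertebra, then applies
#' Gaussian point jitter followed by the spec's pose (roll, yaw, sagittal
#' offset).  The returned truth keeps the noiseless, pose-free trajectory
#' and its per-vertebra curvature computed with an independent
#' arccos-of-dot evaluation.  All randomness derives from \code{spec@seed};
#' the caller's RNG state is left untouched.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param subject subject metadata attached to the trajectory.
#' @return list with elements \code{trajectory}
#'   (\linkS4class{SpineTrajectory}) and \code{truth}
#'   (\linkS4class{PhantomTruth}).
#' @export
makePhantomTrajectory <- function(spec, subject = list()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  pts <- .samplePath(spec)
  clean <- assignIdentities(pts, spec@anchorLabel, spec@anchorIndex,
                            subject = subject)
  truth <- new("PhantomTruth", cleanTrajectory = clean, pose = spec@pose,
               trueCurvature = .truthCurvature(clean))
  traj <- clean
  if (spec@jitterSdMm > 0) {
    old <- .saveRNG(); on.exit(.restoreRNG(old))
    set.seed(spec@seed)
    traj@points <- traj@points +
      matrix(stats::rnorm(length(traj@points), sd = spec@jitterSdMm),
             ncol = 3L)
  }
  traj <- applyPose(traj, roll = spec@pose$roll, yaw = spec@pose$yaw,
                    dx = spec@pose$dx, dz = spec@pose$dz)
  list(trajectory = traj, truth = truth)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Apply a rigid pose to a trajectory
#'
#' Rotates about the trajectory centroid (roll about x, then yaw about
#' z), then translates within the sagittal plane.  This is the forward
#' model of the placement errors that \code{\link{correctPose}} and
#' \code{\link{alignCohort}} undo.
#'
#' @param traj a \linkS4class{SpineTrajectory}.
#' @param roll,yaw rotations in radians.
#' @param dx,dz sagittal translation in mm.
#' @return the posed trajectory.
#' @export
applyPose <- function(traj, roll = 0, yaw = 0, dx = 0, dz = 0) {
  if (roll != 0 || yaw != 0)
    traj <- .rotate(traj, .rotZ(yaw) %*% .rotX(roll))
  .translate(traj, dx = dx, dz = dz)
}

#' Voxelize a phantom trajectory into a micro-CT-like volume
#'
#' Renders one high-intensity ellipsoidal blob (a vertebral body) midway
#' between each pair of consecutive reference points, oriented along the
#' local chord, over a constant background with optional Gaussian noise
#' (clamped at zero).  The gaps at the reference points stay below blob
#' intensity, so intervertebral landmarks remain visible in the stripe
#' lateral projection.  The trajectory is shifted so the bounding box
#' (points plus \code{marginMm}) starts at the world origin, matching the
#' voxel-center convention of \linkS4class{SpineVolume}; the shifted
#' trajectory and offset are returned alongside the volume.  With an
#' explicit \code{boxMm = c(nx, ny, nz)} (mm extents), a trajectory that
#' does not fit (including blob radii) is an error.
#'
#' @param traj a \linkS4class{SpineTrajectory} (typically from
#'   \code{\link{makePhantomTrajectory}}).
#' @param spec the \linkS4class{PhantomSpec} (voxel size, blob and noise
#'   parameters, seed).
#' @param marginMm margin added around the trajectory (mm).
#' @param boxMm optional fixed volume extent in mm, length 3.
#' @return list: \code{volume} (\linkS4class{SpineVolume}),
#'   \code{trajectory} (shifted into the volume frame), \code{offsetMm}
#'   (the applied shift).
#' @export
voxelizePhantom <- function(traj, spec, marginMm = 3, boxMm = NULL) {
  h <- spec@voxelSizeMm
  blob <- spec@blob
  rmax <- max(blob$semiAxesMm)
  p <- traj@points
  lo <- apply(p, 2L, min) - marginMm
  offset <- -lo
  p <- sweep(p, 2L, offset, "+")
  traj@points <- p
  ext <- apply(p, 2L, max) + marginMm
  if (!is.null(boxMm)) {
    if (any(ext > boxMm + 1e-9))
      stop("trajectory (plus margin) exceeds the bounding box: needs ",
           paste(sprintf("%.1f", ext), collapse = " x "), " mm, box is ",
           paste(sprintf("%.1f", boxMm), collapse = " x "), " mm")
    ext <- boxMm
  }
  dims <- pmax(ceiling(ext / h), 2L)
  vol <- array(blob$background, dim = dims)
  if (blob$noiseSd > 0) {
    old <- .saveRNG(); on.exit(.restoreRNG(old))
    set.seed(spec@seed + 1L)  # noise stream derived from the phantom seed
    vol <- vol + stats::rnorm(length(vol), sd = blob$noiseSd)
    vol <- pmax(vol, 0)
    dim(vol) <- dims
  }
  centers <- (p[-1L, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
  chords <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  ax <- blob$semiAxesMm
  for (b in seq_len(nrow(centers))) {
    u <- chords[b, ] / sqrt(sum(chords[b, ]^2))
    w1 <- .cross3(u, c(0, 0, 1))
    if (sum(w1^2) < 1e-12) w1 <- .cross3(u, c(0, 1, 0))
    w1 <- w1 / sqrt(sum(w1^2))
    w2 <- .cross3(u, w1)
    ctr <- centers[b, ]
    idx <- lapply(1:3, function(k) {
      rng <- (ctr[k] + c(-1, 1) * rmax * 1.05) / h + 0.5
      seq(max(1L, floor(rng[1])), min(dims[k], ceiling(rng[2])))
    })
    g <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
    q <- sweep((g - 0.5) * h, 2L, ctr, "-")
    inside <- (q %*% u / ax[1])^2 + (q %*% w1 / ax[2])^2 +
      (q %*% w2 / ax[3])^2 <= 1
    if (any(inside)) {
      gi <- g[inside, , drop = FALSE]
      lin <- gi[, 1L] + dims[1L] * (gi[, 2L] - 1L) +
        dims[1L] * dims[2L] * (gi[, 3L] - 1L)
      vol[lin] <- pmax(vol[lin], blob$intensity)
    }
  }
  list(volume = SpineVolume(vol, voxelSizeMm = h),
       trajectory = traj, offsetMm = offset)
}

#' Synthetic biplanar annotations from a known trajectory
#'
#' Projects the trajectory's reference points into the two annotation
#' planes exactly as an annotator would click their true landmark
#' projections: midline points (x, y) from the horizontal view, lateral
#' points (x, z) from the stripe view, plus the anchor identity of the
#' point nearest the series middle.  Used for end-to-end validation;
#' landmark detection from images is deliberately not performed.
#'
#' @param traj a labeled \linkS4class{SpineTrajectory}.
#' @return list: \code{midline} data.frame (x_mm, y_mm), \code{lateral}
#'   data.frame (x_mm, z_mm), \code{anchorLabel}, \code{anchorIndex}
#'   (row in \code{lateral}).
#' @export
autoAnnotate <- function(traj) {
  p <- traj@points
  i <- as.integer(ceiling(nrow(p) / 2))
  list(midline = data.frame(x_mm = p[, 1L], y_mm = p[, 2L]),
       lateral = data.frame(x_mm = p[, 1L], z_mm = p[, 3L]),
       anchorLabel = traj@labels[i], anchorIndex = i)
}

#' Write a volume to NIfTI
#'
#' @param volume a \linkS4class{SpineVolume}.
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeVolumeNifti <- function(volume, path) {
  img <- RNifti::asNifti(volume@intensities)
  RNifti::pixdim(img) <- rep(volume@voxelSize, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
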