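#' @import methods
NULL

.ANAT_AXES <- c("x", "y", "z")

## Pixel-axis pairs of each anatomical projection plane (row axis, column axis)
## in the right-handed frame: x anterior (towards the nose), y left, z dorsal.
.PLANE_AXES <- list(
  horizontal = c("x", "y"),
  coronal    = c("y", "z"),
  sagittal   = c("x", "z")
)

#' SpineVolume: a 3D micro-CT intensity grid
#'
#' Holds a reconstructed micro-CT volume with isotropic voxel size and an
#' explicit mapping of array dimensions to anatomical axes (x anterior,
#' y left, z dorsal).  The world coordinate of voxel index \code{k}
#' (1-based) along an axis is \code{(k - 0.5) * voxelSize(x)} mm, i.e.
#' voxel centers, with the first voxel face at 0.
#'
#' @slot intensities 3D numeric array of non-negative intensities.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot axisMap character(3); \code{axisMap[i]} names the anatomical axis
#'   stored along array dimension \code{i} (a permutation of "x","y","z").
#' @exportClass SpineVolume
setClass("SpineVolume",
  representation(intensities = "array", voxelSize = "numeric",
                 axisMap = "character"))

setValidity("SpineVolume", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  else if (any(d < 2L))
    msg <- c(msg, "each axis needs at least 2 voxels")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (length(object@axisMap) != 3L ||
      !setequal(object@axisMap, .ANAT_AXES) ||
      anyDuplicated(object@axisMap))
    msg <- c(msg, "axisMap must be a permutation of c('x','y','z')")
  if (anyNA(object@intensities) || any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative and non-missing")
  if (length(msg)) msg else TRUE
})

#' ProjectionImage: a 2D maximum intensity projection
#'
#' @slot pixels numeric matrix; rows/columns follow the plane's axis pair
#'   (horizontal: x by y; coronal: y by z; sagittal: x by z).
#' @slot plane one of "horizontal", "coronal", "sagittal".
#' @slot pixelSize pixel edge length in mm (equals the source voxel size).
#' @slot params list of projection parameters (e.g. stripe width and the
#'   midline knots for stripe-restricted projections).
#' @exportClass ProjectionImage
setClass("ProjectionImage",
  representation(pixels = "matrix", plane = "character",
                 pixelSize = "numeric", params = "list"),
  prototype(params = list()))

setValidity("ProjectionImage", function(object) {
  msg <- character()
  if (!(length(object@plane) == 1L && object@plane %in% names(.PLANE_AXES)))
    msg <- c(msg, "plane must be one of 'horizontal', 'coronal', 'sagittal'")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' MidlineSpline: natural cubic spline approximation of the spinal midline
#'
#' Interpolates medio-lateral position y as a function of antero-posterior
#' position x through annotated midline points, with natural (zero second
#' derivative) boundary conditions.  Evaluation outside the knot range
#' clamps to the nearest endpoint value, so partial midline annotations
#' still serve full-length volumes.
#'
#' @slot knots two-column matrix (x_mm, y_mm) with strictly increasing x.
#' @slot fun the interpolating function of x.
#' @exportClass MidlineSpline
setClass("MidlineSpline",
  representation(knots = "matrix", fun = "function"))

setValidity("MidlineSpline", function(object) {
  k <- object@knots
  if (!is.numeric(k) || ncol(k) != 2L || nrow(k) < 2L)
    return("knots must be a numeric matrix with >= 2 rows and 2 columns")
  if (anyNA(k) || any(!is.finite(k)))
    return("knots must be finite")
  if (any(diff(k[, 1L]) <= 0))
    return("knot x values must be strictly increasing")
  TRUE
})

#' SpineTrajectory: labeled 3D spinal reference points
#'
#' An ordered set of intervertebral reference points (the ventral limit of
#' intervertebral spaces) in mm in the anatomical frame, each labeled with
#' the vertebra immediately anterior to it.  Points are stored from
#' posterior to anterior, so vertebral ordinals (Ce1 = 1 ... Ca_n) strictly
#' decrease by one per step: consecutive points flank exactly one vertebra.
#'
#' @slot points numeric matrix n x 3 with columns x, y, z (mm).
#' @slot labels character vertebra labels (e.g. "L6"), unique.
#' @slot ordinals integer anatomical ordinals matching \code{labels}.
#' @slot subject named list of metadata (animal, genotype, sex, age, ...).
#' @exportClass SpineTrajectory
setClass("SpineTrajectory",
  representation(points = "matrix", labels = "character",
                 ordinals = "integer", subject = "list"),
  prototype(subject = list()))

setValidity("SpineTrajectory", function(object) {
  msg <- character()
  p <- object@points
  n <- nrow(p)
  if (!is.numeric(p) || ncol(p) != 3L || n < 1L)
    msg <- c(msg, "points must be an n x 3 numeric matrix with n >= 1")
  if (anyNA(p) || any(!is.finite(p)))
    msg <- c(msg, "points must be finite")
  if (length(object@labels) != n || length(object@ordinals) != n)
    msg <- c(msg, "labels and ordinals must match the number of points")
  if (n > 1L && length(object@ordinals) == n &&
      any(diff(object@ordinals) != -1L))
    msg <- c(msg,
      "ordinals must decrease by exactly 1 posterior to anterior")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "vertebra labels must be unique")
  if (length(msg)) msg else TRUE
})

#' PoseParameters: accumulated pose correction
#'
#' @slot roll accumulated rotation about x (radians).
#' @slot yaw accumulated rotation about z (radians).
#' @slot iterations number of alternating minimization sweeps performed.
#' @slot converged logical; update fell below tolerance.
#' @slot degenerate logical; input had no lateral/dorsal extent, identity
#'   pose returned.
#' @exportClass PoseParameters
setClass("PoseParameters",
  representation(roll = "numeric", yaw = "numeric", iterations = "integer",
                 converged = "logical", degenerate = "logical"))

#' CohortAlignment: result of iterative sagittal cohort alignment
#'
#' @slot aligned list of \linkS4class{SpineTrajectory} after alignment.
#' @slot meanPoints data.frame of per-label mean position and per-coordinate
#'   sample SD over the trajectories containing that label.
#' @slot iterations iterations run (including the converging one).
#' @slot finalObjective final sum of squared distances (mm^2) of
#'   shared-label points to their per-label mean.
#' @slot objectiveTrace objective value after each iteration.
#' @slot converged logical.
#' @exportClass CohortAlignment
setClass("CohortAlignment",
  representation(aligned = "list", meanPoints = "data.frame",
                 iterations = "integer", finalObjective = "numeric",
                 objectiveTrace = "numeric", converged = "logical"))

#' CurvatureProfile: signed curvature angle per vertebral level
#'
#' The local curvature at vertebra i is the signed angle (degrees) between
#' the longitudinal axes of its posterior and anterior neighbor vertebrae;
#' the first and last flanked vertebrae carry no angle.  Positive angles
#' are dorsal convexities (kyphosis) under the default sign rule.
#'
#' @slot vertebrae character vertebra labels, posterior to anterior.
#' @slot ordinals matching anatomical ordinals.
#' @slot angles signed curvature angles in degrees.
#' @slot subject named list of metadata carried over from the trajectory.
#' @exportClass CurvatureProfile
setClass("CurvatureProfile",
  representation(vertebrae = "character", ordinals = "integer",
                 angles = "numeric", subject = "list"),
  prototype(subject = list()))

setValidity("CurvatureProfile", function(object) {
  n <- length(object@vertebrae)
  if (length(object@angles) != n || length(object@ordinals) != n)
    return("vertebrae, ordinals and angles must have equal length")
  TRUE
})

#' PhantomSpec: parametric description of a synthetic spine
#'
#' Defaults describe the cohort conditions used throughout validation:
#' 26 reference points at 2.5 mm arc spacing covering T4..Ca6, one dorsal
#' Gaussian kyphosis bump (amplitude 4 mm, SD width 10 mm) over the
#' thoracic band, point jitter SD 0.1 mm, 125 um isotropic voxels.
#'
#' @slot nVertebrae number of reference points (>= 4).
#' @slot spacingMm arc-length spacing between reference points (mm).
#' @slot sagittalProfile list describing z(x): either
#'   \code{list(type = "gaussians", bumps = data.frame(amplitude, center,
#'   width))} (width = Gaussian SD, mm) or \code{list(type = "arc",
#'   radius = R)} for an exact circular arc in the sagittal plane.
#' @slot lateralProfile same structure for y(x) ("gaussians" only), or an
#'   empty list for a straight medio-lateral course.
#' @slot pose named list roll, yaw (radians), dx, dz (mm) applied after
#'   jitter, about the trajectory centroid.
#' @slot jitterSdMm SD of isotropic Gaussian point jitter (mm).
#' @slot seed integer seed fixing all phantom randomness.
#' @slot voxelSizeMm voxel size for voxelization (mm).
#' @slot anchorLabel,anchorIndex vertebral identity anchor: point number
#'   \code{anchorIndex} (posterior to anterior, 1-based) carries
#'   \code{anchorLabel}.
#' @slot blob list: \code{semiAxesMm} (length-3, along/left/dorsal of the
#'   local chord), \code{intensity}, \code{background}, \code{noiseSd} for
#'   voxelization.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(nVertebrae = "integer", spacingMm = "numeric",
                 sagittalProfile = "list", lateralProfile = "list",
                 pose = "list", jitterSdMm = "numeric", seed = "integer",
                 voxelSizeMm = "numeric", anchorLabel = "character",
                 anchorIndex = "integer", blob = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nVertebrae < 4L)
    msg <- c(msg, "nVertebrae must be >= 4")
  if (object@spacingMm <= 0) msg <- c(msg, "spacingMm must be positive")
  if (object@jitterSdMm < 0) msg <- c(msg, "jitterSdMm must be >= 0")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be positive")
  pr <- object@sagittalProfile
  if (length(pr) && !identical(pr$type, "gaussians") &&
      !identical(pr$type, "arc"))
    msg <- c(msg, "sagittalProfile$type must be 'gaussians' or 'arc'")
  if (identical(pr$type, "gaussians") && any(pr$bumps$width <= 0))
    msg <- c(msg, "gaussian bump widths must be positive")
  if (identical(pr$type, "arc") && pr$radius <= 0)
    msg <- c(msg, "arc radius must be positive")
  if (!(object@anchorIndex >= 1L && object@anchorIndex <= object@nVertebrae))
    msg <- c(msg, "anchorIndex must lie within 1..nVertebrae")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth retained by the phantom generator
#'
#' Truth is computed from the noiseless, pose-free trajectory only; the
#' true per-vertebra curvature uses an arccos-of-dot-product evaluation
#' kept deliberately separate from the production curvature code path.
#'
#' @slot cleanTrajectory the labeled pre-jitter, pre-pose trajectory.
#' @slot pose applied pose list (roll, yaw, dx, dz).
#' @slot trueCurvature data.frame (vertebra, ordinal, angle_deg).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(cleanTrajectory = "SpineTrajectory", pose = "list",
                 trueCurvature = "data.frame"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "SpineVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("SpineVolume: %d x %d x %d voxels (%.4g mm isotropic)\n",
              d[1], d[2], d[3], object@voxelSize))
  cat("  axis map:", paste(sprintf("dim%d=%s", 1:3, object@axisMap),
                           collapse = ", "), "\n")
})

setMethod("show", "ProjectionImage", function(object) {
  ax <- .PLANE_AXES[[object@plane]]
  cat(sprintf("ProjectionImage (%s, %s by %s): %d x %d px, %.4g mm/px\n",
              object@plane, ax[1], ax[2], nrow(object@pixels),
              ncol(object@pixels), object@pixelSize))
})

setMethod("show", "MidlineSpline", function(object) {
  k <- object@knots
  cat(sprintf("MidlineSpline: %d knots, x in [%.3g, %.3g] mm (natural cubic)\n",
              nrow(k), k[1, 1], k[nrow(k), 1]))
})

setMethod("show", "SpineTrajectory", function(object) {
  n <- nrow(object@points)
  cat(sprintf("SpineTrajectory: %d reference points (%s .. %s)\n",
              n, object@labels[1], object@labels[n]))
  if (length(object@subject))
    cat("  subject:", paste(names(object@subject), unlist(object@subject),
                            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PoseParameters", function(object) {
  cat(sprintf(
    "PoseParameters: roll %.4f deg, yaw %.4f deg (%d iterations%s%s)\n",
    object@roll * 180 / pi, object@yaw * 180 / pi, object@iterations,
    if (object@converged) ", converged" else "",
    if (object@degenerate) ", degenerate input" else ""))
})

setMethod("show", "CohortAlignment", function(object) {
  cat(sprintf(
    "CohortAlignment: %d trajectories, %d iterations, objective %.6g mm^2\n",
    length(object@aligned), object@iterations, object@finalObjective))
})

setMethod("show", "CurvatureProfile", function(object) {
  cat(sprintf("CurvatureProfile: %d vertebrae (%s .. %s), range [%.2f, %.2f] deg\n",
              length(object@vertebrae), object@vertebrae[1],
              object@vertebrae[length(object@vertebrae)],
              min(object@angles), max(object@angles)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d points, %.3g mm spacing, jitter %.3g mm, seed %d\n",
    object@nVertebrae, object@spacingMm, object@jitterSdMm, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d labeled points, %d true curvature angles\n",
              nrow(object@cleanTrajectory@points),
              nrow(object@trueCurvature)))
})
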