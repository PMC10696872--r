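#' @include AllClasses.R vertebrae.R
NULL

#' Construct a SpineTrajectory from labeled points
#'
#' Points are re-ordered posterior to anterior (descending ordinal).
#' Labels must form a consecutive anatomical run (one vertebra between
#' consecutive reference points).
#'
#' @param points n x 3 numeric matrix (x, y, z in mm).
#' @param labels character vertebra labels, one per point.
#' @param subject named list of subject metadata (animal, genotype, sex,
#'   age, ...), kept as opaque strings.
#' @param formula vertebral formula, see \code{\link{mouseVertebralFormula}}.
#' @return a \linkS4class{SpineTrajectory}.
#' @export
SpineTrajectory <- function(points, labels, subject = list(),
                            formula = mouseVertebralFormula) {
  points <- as.matrix(points)
  ords <- vertebraOrdinal(labels, formula)
  ord <- order(ords, decreasing = TRUE)  # posterior first
  new("SpineTrajectory", points = unname(points[ord, , drop = FALSE]),
      labels = labels[ord], ordinals = ords[ord], subject = subject)
}

#' Assign vertebral identities to an ordered point series
#'
#' Given 3D reference points sorted from posterior to anterior (ascending
#' x in a prone animal) and the identity of one anchor point, labels every
#' point by walking the vertebral formula: anterior steps go
#' ...L6 -> L5 -> ... -> L1 -> T13 -> ... -> T1 -> Ce7 -> ... -> Ce1,
#' posterior steps go L6 -> S1 -> ... -> S4 -> Ca1 -> Ca2 -> ...
#' Each reference point is labeled with the vertebra immediately anterior
#' to it (the "L6" point sits at the posterior end of L6).  Caudal labels
#' extend indefinitely; walking anterior past Ce1 is an error.
#'
#' @param points3d n x 3 matrix of (x, y, z) mm, sorted by ascending x
#'   (posterior to anterior).  A non-monotone x series is rejected.
#' @param anchor vertebra label of the anchor point, e.g. "L6".
#' @param anchorIndex 1-based index of the anchor point within
#'   \code{points3d}.
#' @param subject,formula see \code{\link{SpineTrajectory}}.
#' @return a \linkS4class{SpineTrajectory}.
#' @examples
#' pts <- cbind(seq(0, 62.5, by = 2.5), 0, 0)
#' traj <- assignIdentities(pts, "L6", 11)
#' vertebraLabels(traj)[10:12]   # "S1" "L6" "L5"
#' @export
assignIdentities <- function(points3d, anchor, anchorIndex,
                             subject = list(),
                             formula = mouseVertebralFormula) {
  points3d <- as.matrix(points3d)
  n <- nrow(points3d)
  if (!(anchorIndex >= 1L && anchorIndex <= n))
    stop("anchorIndex must be in 1..", n)
  if (n > 1L && any(diff(points3d[, 1L]) <= 0))
    stop("reference points must have strictly increasing x ",
         "(posterior to anterior); sort or re-annotate first")
  anchorOrd <- vertebraOrdinal(anchor, formula)
  ords <- anchorOrd - (seq_len(n) - anchorIndex)  # x up = anterior = ordinal down
  if (any(ords < 1L))
    stop("too many points anterior of the anchor: the vertebral formula ",
         "is exhausted anterior to Ce1 at point ",
         which(ords < 1L)[1L])
  labels <- vertebraLabel(ords, formula)
  new("SpineTrajectory", points = unname(points3d), labels = labels,
      ordinals = as.integer(ords), subject = subject)
}

#' Build a labeled 3D trajectory from biplanar annotations
#'
#' Combines the two annotation sets of the biplanar workflow: horizontal
#' midline points give the midline spline; lateral reference points (x, z)
#' are lifted to 3D through it; the anchor vertebra propagates identities
#' to every point.
#'
#' @param midline two-column (x_mm, y_mm) midline annotations.
#' @param refpoints two-column (x_mm, z_mm) lateral reference-point
#'   annotations; rows are sorted by x internally.
#' @param anchor vertebra label of the anchor reference point.
#' @param anchorIndex 1-based row index of the anchor within
#'   \code{refpoints} as given (remapped internally if sorting reorders
#'   rows).
#' @param subject,formula see \code{\link{SpineTrajectory}}.
#' @return a \linkS4class{SpineTrajectory}.
#' @export
buildTrajectory <- function(midline, refpoints, anchor, anchorIndex,
                            subject = list(),
                            formula = mouseVertebralFormula) {
  sp <- fitMidline(midline)
  rp <- as.matrix(refpoints)
  ord <- order(rp[, 1L])
  rp <- rp[ord, , drop = FALSE]
  anchorIndex <- match(anchorIndex, ord)
  lifted <- liftPoints(rp, sp)
  assignIdentities(lifted, anchor, anchorIndex, subject = subject,
                   formula = formula)
}

## shift/rotate helpers shared by alignment and phantom code
.translate <- function(traj, dx = 0, dy = 0, dz = 0) {
  traj@points <- sweep(traj@points, 2L, c(dx, dy, dz), "+")
  traj
}

.rotate <- function(traj, R, center = colMeans(traj@points)) {
  traj@points <- sweep(sweep(traj@points, 2L, center, "-") %*% t(R),
                       2L, center, "+")
  traj
}

.rotX <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a),  cos(a)), 3, 3, byrow = TRUE)

.rotZ <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a),  cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)
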