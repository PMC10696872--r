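#' @include AllClasses.R
NULL

## Permute intensities so array dims are (x, y, z) anatomical order.
.anatArray <- function(volume) {
  perm <- match(.ANAT_AXES, volume@axisMap)
  aperm(volume@intensities, perm)
}

#' Maximum intensity projection of a volume
#'
#' Collapses the volume along the axis orthogonal to the requested
#' anatomical plane, each pixel taking the maximum intensity along its
#' projection ray.  The horizontal (x-y, top view) projection is the one
#' used to annotate the spinal midline; sagittal (x-z) is the side view,
#' coronal (y-z) the front view.
#'
#' @param volume a \linkS4class{SpineVolume}.
#' @param plane "horizontal", "coronal" or "sagittal".
#' @return a \linkS4class{ProjectionImage} oriented per the anatomical
#'   axis pair of the plane.
#' @export
mip <- function(volume, plane = c("horizontal", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  A <- .anatArray(volume)
  margins <- switch(plane,
    horizontal = c(1L, 2L),   # project along z
    coronal    = c(2L, 3L),   # project along x
    sagittal   = c(1L, 3L))   # project along y
  px <- apply(A, margins, max)
  new("ProjectionImage", pixels = px, plane = plane,
      pixelSize = volume@voxelSize, params = list())
}

#' Stripe-restricted lateral (sagittal) maximum intensity projection
#'
#' Computes a lateral MIP from a thin vertical stripe of voxels centered
#' on the spinal midline: voxel columns whose y-center lies within
#' \code{widthMm / 2} of the midline spline evaluated at the column's
#' x-center.  Restricting the projection to the stripe keeps the spinal
#' canal and intervertebral spaces visible instead of being buried under
#' ribs and limbs.  Columns with x outside the spline domain use the
#' nearest-endpoint spline value, so a partial midline annotation still
#' yields a full-length image; a column whose stripe contains no voxel is
#' set to 0.
#'
#' @param volume a \linkS4class{SpineVolume}.
#' @param spline a \linkS4class{MidlineSpline} fitted on the horizontal
#'   projection.
#' @param widthMm full stripe width in mm (default 1.0, i.e. 8 voxels at
#'   125 um).
#' @return a sagittal \linkS4class{ProjectionImage}; \code{params} records
#'   the stripe width.
#' @export
stripeLateralMip <- function(volume, spline, widthMm = 1.0) {
  stopifnot(widthMm > 0)
  A <- .anatArray(volume)
  h <- volume@voxelSize
  nx <- dim(A)[1]; ny <- dim(A)[2]; nz <- dim(A)[3]
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  fy <- evalMidline(spline, xc)
  out <- matrix(0, nx, nz)
  nonEmpty <- FALSE
  half <- widthMm / 2
  for (i in seq_len(nx)) {
    sel <- which(abs(yc - fy[i]) <= half)
    if (!length(sel)) next
    nonEmpty <- TRUE
    out[i, ] <- if (length(sel) == 1L) A[i, sel, ]
      else do.call(pmax, lapply(sel, function(j) A[i, j, ]))
  }
  if (!nonEmpty)
    stop("stripe is empty for every column: widthMm (", widthMm,
         " mm) is below the voxel size or the midline lies off the grid")
  new("ProjectionImage", pixels = out, plane = "sagittal",
      pixelSize = h,
      params = list(stripe_width_mm = widthMm,
                    midline_knots = unname(spline@knots)))
}
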