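#' @include AllClasses.R
NULL

#' Thresholded bright area of one MR slice
#'
#' Ventricles filled with CSF appear as white patches in T2-weighted MR
#' slices; their area is the count of pixels at or above a greyscale
#' threshold (optionally restricted to a region of interest) times the
#' pixel area.  Pre-drawn binary masks can be passed directly with
#' \code{threshold} at any value reached by the mask (e.g. 1).
#'
#' @param image 2D numeric matrix (greyscale slice or 0/1 mask).
#' @param threshold greyscale cut-off; pixels >= threshold count.
#' @param pixelSizeMm in-plane pixel edge length (mm); MR headers or
#'   acquisition config must supply it.
#' @param roi optional logical/0-1 matrix of the same shape restricting
#'   the count.
#' @return area in mm^2.
#' @export
sliceArea <- function(image, threshold, pixelSizeMm, roi = NULL) {
  image <- as.matrix(image)
  stopifnot(pixelSizeMm > 0)
  hit <- image >= threshold
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (!identical(dim(roi), dim(image)))
      stop("roi shape ", paste(dim(roi), collapse = "x"),
           " does not match image shape ",
           paste(dim(image), collapse = "x"))
    hit <- hit & (roi != 0)
  }
  sum(hit) * pixelSizeMm^2
}

#' Volume of a slice series: total area times slice thickness
#'
#' @param areas numeric vector of per-slice areas (mm^2), non-negative.
#' @param sliceThicknessMm slice thickness in mm; default 0.6, the
#'   acquisition thickness of the axial T2 series this rule was designed
#'   for.
#' @return volume in mm^3 (0 for an empty series).
#' @examples
#' seriesVolume(c(1, 2, 3))   # 3.6 mm^3
#' @export
seriesVolume <- function(areas, sliceThicknessMm = 0.6) {
  stopifnot(sliceThicknessMm > 0)
  if (length(areas) && any(areas < 0))
    stop("slice areas must be non-negative")
  sum(areas) * sliceThicknessMm
}

#' Mean cross-sectional area over a slice series
#'
#' Used e.g. to compare overall brain size as the average brain area
#' across MR cross sections.
#'
#' @param areas numeric vector of per-slice areas (mm^2), non-empty.
#' @return mean area in mm^2.
#' @export
meanSliceArea <- function(areas) {
  if (!length(areas)) stop("no slice areas given")
  mean(areas)
}
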