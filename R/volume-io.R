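#' @include AllClasses.R
NULL

#' Construct a SpineVolume from an array
#'
#' @param intensities 3D numeric array of non-negative intensities.
#' @param voxelSizeMm isotropic voxel edge length in mm (default 0.125,
#'   i.e. the 125 um reconstruction resolution typical of small-animal
#'   micro-CT).
#' @param axisMap character(3) assigning anatomical axes to array
#'   dimensions; default \code{c("x","y","z")} (dim 1 antero-posterior,
#'   dim 2 medio-lateral, dim 3 dorso-ventral).
#' @return a \linkS4class{SpineVolume}.
#' @export
SpineVolume <- function(intensities, voxelSizeMm = 0.125,
                        axisMap = c("x", "y", "z")) {
  new("SpineVolume", intensities = intensities,
      voxelSize = as.numeric(voxelSizeMm), axisMap = axisMap)
}

#' Read a micro-CT volume from NIfTI or multi-page TIFF
#'
#' NIfTI files (.nii, .nii.gz) carry voxel spacing in their header; the
#' spacing must be isotropic (the downstream geometry assumes cubic
#' voxels).  TIFF stacks carry no reliable spacing, so \code{voxelSizeMm}
#' is required for them.  An explicitly supplied \code{voxelSizeMm} is
#' only used when the header has none.
#'
#' @param path path to a .nii, .nii.gz, .tif or .tiff file.
#' @param voxelSizeMm voxel size in mm; required for TIFF input.
#' @param axisMap anatomical axis of each array dimension (see
#'   \code{\link{SpineVolume}}).
#' @return a \linkS4class{SpineVolume}.
#' @export
readVolume <- function(path, voxelSizeMm = NULL, axisMap = c("x", "y", "z")) {
  if (!file.exists(path))
    stop("volume file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    pix <- RNifti::pixdim(img)[seq_len(3)]
    if (any(pix > 0)) {
      if (diff(range(pix)) > 1e-6 * max(pix))
        stop("anisotropic NIfTI voxel spacing (",
             paste(signif(pix, 6), collapse = " x "),
             " mm); the pipeline assumes isotropic voxels")
      vs <- pix[1]
    } else if (!is.null(voxelSizeMm)) {
      vs <- voxelSizeMm
    } else {
      stop("NIfTI header carries no voxel spacing; supply voxelSizeMm")
    }
    arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  } else if (grepl("\\.tiff?$", lower)) {
    if (is.null(voxelSizeMm))
      stop("TIFF stacks carry no reliable voxel spacing; ",
           "voxelSizeMm must be supplied")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra channels
      p
    }))
    vs <- voxelSizeMm
  } else {
    stop("unsupported volume format (expect .nii, .nii.gz, .tif, .tiff): ",
         path)
  }
  SpineVolume(arr, voxelSizeMm = vs, axisMap = axisMap)
}

#' Write a projection image to TIFF with a JSON sidecar
#'
#' Pixels are rescaled to [0, 1] for the 32-bit float TIFF; the sidecar
#' (\code{<path>.json}) records the plane, pixel size, intensity range and
#' any stripe parameters so the projection is self-describing.
#'
#' @param image a \linkS4class{ProjectionImage}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeProjection <- function(image, path) {
  px <- image@pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  side <- c(list(plane = image@plane, pixel_size_mm = image@pixelSize,
                 intensity_min = rng[1], intensity_max = rng[2]),
            image@params)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
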