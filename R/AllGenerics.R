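#' @include AllClasses.R
NULL

#' Accessors for spinetrace objects
#'
#' Small accessor generics: \code{voxelSize} and \code{axisMap} for
#' \linkS4class{SpineVolume}; \code{pixels}, \code{plane} and
#' \code{pixelSize} for \linkS4class{ProjectionImage}; \code{refPoints},
#' \code{vertebraLabels} and \code{subjectInfo} for
#' \linkS4class{SpineTrajectory} / \linkS4class{CurvatureProfile};
#' \code{alignedTrajectories} for \linkS4class{CohortAlignment};
#' \code{angles} returns the named signed angle vector of a profile.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("axisMap", function(x) standardGeneric("axisMap"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("plane", function(x) standardGeneric("plane"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("refPoints", function(x) standardGeneric("refPoints"))

#' @rdname accessors
#' @export
setGeneric("vertebraLabels", function(x) standardGeneric("vertebraLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectInfo", function(x) standardGeneric("subjectInfo"))

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("alignedTrajectories",
           function(x) standardGeneric("alignedTrajectories"))

#' @rdname accessors
#' @export
setMethod("voxelSize", "SpineVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("axisMap", "SpineVolume", function(x) x@axisMap)

#' @rdname accessors
#' @export
setMethod("intensities", "SpineVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("pixels", "ProjectionImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("plane", "ProjectionImage", function(x) x@plane)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ProjectionImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("refPoints", "SpineTrajectory", function(x) {
  p <- x@points
  dimnames(p) <- list(x@labels, c("x", "y", "z"))
  p
})

#' @rdname accessors
#' @export
setMethod("vertebraLabels", "SpineTrajectory", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("vertebraLabels", "CurvatureProfile", function(x) x@vertebrae)

#' @rdname accessors
#' @export
setMethod("subjectInfo", "SpineTrajectory", function(x) x@subject)

#' @rdname accessors
#' @export
setMethod("subjectInfo", "CurvatureProfile", function(x) x@subject)

#' @rdname accessors
#' @export
setMethod("angles", "CurvatureProfile", function(x) {
  stats::setNames(x@angles, x@vertebrae)
})

#' @rdname accessors
#' @export
setMethod("alignedTrajectories", "CohortAlignment", function(x) x@aligned)
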