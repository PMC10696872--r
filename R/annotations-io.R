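#' @include trajectory.R
NULL

#' Read biplanar annotation CSV files
#'
#' \code{readMidlineCSV} expects columns \code{image, x_mm, y_mm};
#' \code{readRefPointsCSV} expects \code{image, x_mm, z_mm} plus an
#' optional \code{label} column in which exactly one row names the anchor
#' vertebra (all other entries empty).  Annotations are in mm in the
#' anatomical frame; \code{\link{pixelsToMm}} converts pixel-unit clicks.
#'
#' @param path CSV file path.
#' @return \code{readMidlineCSV}: data.frame (image, x_mm, y_mm);
#'   \code{readRefPointsCSV}: data.frame (image, x_mm, z_mm) with
#'   attributes \code{anchorLabel} and \code{anchorIndex} when a label
#'   column is present.
#' @export
readMidlineCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x_mm", "y_mm")
  if (!all(req %in% names(df)))
    stop("midline CSV needs columns x_mm, y_mm: ", path)
  df
}

#' @rdname readMidlineCSV
#' @export
readRefPointsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x_mm", "z_mm")
  if (!all(req %in% names(df)))
    stop("reference-point CSV needs columns x_mm, z_mm: ", path)
  if ("label" %in% names(df)) {
    lab <- trimws(as.character(df$label))
    hit <- which(!is.na(lab) & nzchar(lab))
    if (length(hit) != 1L)
      stop("exactly one reference-point row must carry the anchor label; ",
           "found ", length(hit), " in ", path)
    attr(df, "anchorLabel") <- lab[hit]
    attr(df, "anchorIndex") <- hit
  }
  df
}

#' Convert annotation clicks from pixels to mm
#'
#' Projection images map pixel index k (1-based) to the world coordinate
#' (k - 0.5) * pixel size, consistent with voxel centers.
#'
#' @param px numeric pixel indices (1-based).
#' @param pixelSizeMm pixel size in mm.
#' @return positions in mm.
#' @export
pixelsToMm <- function(px, pixelSizeMm) (px - 0.5) * pixelSizeMm

#' Read and write trajectory CSV files
#'
#' Trajectory tables have columns \code{animal, label, x_mm, y_mm, z_mm},
#' one row per labeled reference point; this is also the hand-off format
#' for external statistics tools.
#'
#' @param traj a \linkS4class{SpineTrajectory}.
#' @param path CSV file path.
#' @param formula vertebral formula used to re-derive ordinals on read.
#' @return \code{writeTrajectoryCSV}: the path, invisibly;
#'   \code{readTrajectoryCSV}: a \linkS4class{SpineTrajectory}.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- data.frame(
    animal = if (is.null(traj@subject$animal)) "" else traj@subject$animal,
    label = traj@labels,
    x_mm = traj@points[, 1L], y_mm = traj@points[, 2L],
    z_mm = traj@points[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path, formula = mouseVertebralFormula) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(df)))
    stop("trajectory CSV needs columns label, x_mm, y_mm, z_mm: ", path)
  subject <- if ("animal" %in% names(df) && !is.na(df$animal[1L]) &&
                 nzchar(df$animal[1L]))
    list(animal = as.character(df$animal[1L])) else list()
  SpineTrajectory(cbind(df$x_mm, df$y_mm, df$z_mm), df$label,
                  subject = subject, formula = formula)
}
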