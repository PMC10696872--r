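#' @include trajectory.R
NULL

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Per-vertebra longitudinal axis vectors
#'
#' Each vertebra flanked by a pair of consecutive reference points gets a
#' unit 3-vector pointing anterior: the normalized difference between its
#' anterior and posterior flanking points.  The posterior flank is the
#' point labeled with that vertebra (reference points sit at the
#' posterior end of the vertebra they are named after), the anterior
#' flank is the next point anterior.
#'
#' @param traj a \linkS4class{SpineTrajectory} with >= 2 points.
#' @return data.frame (vertebra, ordinal, vx, vy, vz), posterior to
#'   anterior; one row per flanked vertebra (n points give n - 1 axes).
#' @export
vertebraAxes <- function(traj) {
  p <- traj@points
  n <- nrow(p)
  if (n < 2L) stop("at least 2 reference points are needed for an axis")
  d <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12))
    stop("coincident flanking points around vertebra ",
         traj@labels[which(len < 1e-12)[1L]])
  v <- d / len
  data.frame(vertebra = traj@labels[-n], ordinal = traj@ordinals[-n],
             vx = v[, 1L], vy = v[, 2L], vz = v[, 3L])
}

#' Signed curvature angle between two vertebral axes
#'
#' The angle magnitude between the longitudinal axes of the vertebrae
#' posterior and anterior to the one of interest, computed as
#' atan2(||vPrev x vNext||, vPrev . vNext) and reported in degrees.  For
#' acute angles (all physiological spines) this equals the arcsine of the
#' cross-product norm; the atan2 form stays correct beyond 90 degrees.
#' The sign is that of the y (leftward) component of vPrev x vNext, which
#' makes dorsally convex (kyphotic) sagittal bends positive in the
#' x-anterior / y-left / z-dorsal frame; pass \code{flipSign = TRUE} for
#' the opposite convention.
#'
#' @param vPrev,vNext unit 3-vectors (posterior and anterior neighbor
#'   axes); unit norm enforced to 1e-6.
#' @param flipSign flip the sign convention.
#' @return signed angle in degrees.
#' @examples
#' a <- 15 * pi / 180
#' curvatureAngle(c(cos(a), 0, sin(a)), c(cos(a), 0, -sin(a)))  # +30
#' @export
curvatureAngle <- function(vPrev, vNext, flipSign = FALSE) {
  for (v in list(vPrev, vNext))
    if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
      stop("curvatureAngle expects unit vectors (|norm - 1| <= 1e-6)")
  cr <- .cross3(vPrev, vNext)
  mag <- atan2(sqrt(sum(cr^2)), sum(vPrev * vNext)) * 180 / pi
  s <- if (cr[2L] < 0) -1 else 1
  if (flipSign) s <- -s
  s * mag
}

#' Per-animal curvature profile
#'
#' Signed curvature angle at every vertebra whose posterior and anterior
#' neighbor axes both exist (the first and last flanked vertebrae carry
#' no angle): with n reference points there are n - 1 axes and n - 3
#' angles.  Curvature is invariant under rigid motions of the trajectory,
#' so centering, pose correction and cohort alignment do not change it.
#'
#' @param traj a \linkS4class{SpineTrajectory} with >= 4 points.
#' @param flipSign see \code{\link{curvatureAngle}}.
#' @return a \linkS4class{CurvatureProfile}.
#' @export
curvatureProfile <- function(traj, flipSign = FALSE) {
  ax <- vertebraAxes(traj)
  m <- nrow(ax)
  if (m < 3L)
    stop("curvature needs >= 4 reference points (>= 3 vertebra axes)")
  V <- as.matrix(ax[, c("vx", "vy", "vz")])
  mid <- seq(2L, m - 1L)
  ang <- vapply(mid, function(j)
    curvatureAngle(V[j - 1L, ], V[j + 1L, ], flipSign = flipSign), 0)
  new("CurvatureProfile", vertebrae = ax$vertebra[mid],
      ordinals = as.integer(ax$ordinal[mid]), angles = ang,
      subject = traj@subject)
}

#' Group curvature profiles as mean, SD and n per vertebral level
#'
#' Groups profiles by subject-metadata keys (e.g. genotype, sex, age) and
#' summarizes each group's angle at each vertebra by arithmetic mean,
#' sample SD (NA when n = 1) and count over the profiles containing that
#' vertebra.
#'
#' @param profiles list of \linkS4class{CurvatureProfile}.
#' @param groupBy character vector of metadata keys; missing keys group
#'   as "NA".  Empty \code{groupBy} summarizes all profiles together.
#' @return data.frame (group, vertebra, ordinal, mean_deg, sd_deg, n),
#'   posterior to anterior within group.
#' @export
groupProfiles <- function(profiles, groupBy = character()) {
  if (!length(profiles)) stop("no profiles to summarize")
  keyOf <- function(p) {
    if (!length(groupBy)) return("all")
    vals <- vapply(groupBy, function(k) {
      v <- p@subject[[k]]
      if (is.null(v)) "NA" else as.character(v)
    }, "")
    paste(vals, collapse = "/")
  }
  keys <- vapply(profiles, keyOf, "")
  out <- lapply(unique(keys), function(key) {
    grp <- profiles[keys == key]
    ords <- sort(unique(unlist(lapply(grp, slot, "ordinals"))),
                 decreasing = TRUE)
    rows <- lapply(ords, function(o) {
      a <- unlist(lapply(grp, function(p) p@angles[match(o, p@ordinals)]))
      a <- a[!is.na(a)]
      data.frame(group = key, vertebra = vertebraLabel(o), ordinal = o,
                 mean_deg = mean(a),
                 sd_deg = if (length(a) > 1L) stats::sd(a) else NA_real_,
                 n = length(a))
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write per-animal curvature angles to CSV
#'
#' One row per (animal, vertebra, angle_deg); the hand-off table for
#' external statistics (mixed models etc. are out of scope here).
#'
#' @param profiles list of \linkS4class{CurvatureProfile}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCurvatureCSV <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      animal = if (is.null(p@subject$animal)) "" else p@subject$animal,
      vertebra = p@vertebrae, angle_deg = p@angles)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
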