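#' @include trajectory.R
NULL

#' Center a trajectory at the origin
#'
#' Subtracts the centroid of the reference points, the first step of pose
#' correction.
#'
#' @param traj a \linkS4class{SpineTrajectory}.
#' @return the centered trajectory.
#' @export
centerTrajectory <- function(traj) {
  .translate(traj, dx = -mean(traj@points[, 1L]),
             dy = -mean(traj@points[, 2L]),
             dz = -mean(traj@points[, 3L]))
}

#' Correct animal pose by roll and yaw minimizing lateral spread
#'
#' Corrects the small lateral tilt and slantwise placement that are
#' unavoidable when positioning an animal on the scanner bed: the
#' trajectory is centered, then the roll (about x) and yaw (about z)
#' rotations minimizing the sum of squared y coordinates are computed and
#' applied, iterating until the update angles fall below \code{tol}.
#'
#' The combined correction Rz(yaw) Rx(roll) sends a unit direction m =
#' (sin yaw, cos yaw cos roll, -cos yaw sin roll) onto the y axis, and m
#' ranges over the whole sphere as (roll, yaw) vary, so the minimizer of
#' sum(y^2) is exactly the smallest principal axis of the point scatter
#' matrix: the corrective angles come in closed form from its smallest
#' eigenvector (global optimum, no risk of the local minima that plague
#' axis-at-a-time descent when the lateral deviation is large).  Repeated
#' sweeps re-estimate on the corrected points; the second sweep is the
#' identity up to round-off.
#'
#' @param traj a \linkS4class{SpineTrajectory}.
#' @param tol convergence tolerance on the update angle (radians).
#' @param maxIter maximum number of sweeps.
#' @return list with elements \code{trajectory} (corrected) and
#'   \code{pose} (\linkS4class{PoseParameters}: accumulated roll/yaw in
#'   radians, sweeps, convergence and degeneracy flags).  A trajectory
#'   collinear with the x axis has no well-defined roll/yaw and returns
#'   the identity pose with \code{degenerate = TRUE} and a warning.
#' @export
correctPose <- function(traj, tol = 1e-8, maxIter = 50L) {
  traj <- centerTrajectory(traj)
  p <- traj@points
  if (sum(p[, 2L]^2 + p[, 3L]^2) < 1e-24) {
    warning("trajectory is collinear with the x axis; ",
            "pose is undetermined, returning identity")
    traj@points <- p
    return(list(trajectory = traj,
                pose = new("PoseParameters", roll = 0, yaw = 0,
                           iterations = 0L, converged = TRUE,
                           degenerate = TRUE)))
  }
  roll <- 0; yaw <- 0; it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    m <- eigen(crossprod(p), symmetric = TRUE)$vectors[, 3L]
    if (m[2L] < 0) m <- -m            # keep corrective angles in +-pi/2
    ty <- asin(max(-1, min(1, m[1L])))  # yaw
    tr <- atan2(-m[3L], m[2L])          # roll
    p <- p %*% t(.rotZ(ty) %*% .rotX(tr))
    roll <- roll + tr
    yaw <- yaw + ty
    if (max(abs(tr), abs(ty)) < tol) { converged <- TRUE; break }
  }
  traj@points <- p
  list(trajectory = traj,
       pose = new("PoseParameters", roll = roll, yaw = yaw,
                  iterations = it, converged = converged,
                  degenerate = FALSE))
}

## Minimize C + 2*(dx*Sx + dz*Sz) + n*(dx^2 + dz^2) over a grid of
## sagittal translations; ties go to the smallest-magnitude translation,
## then lexicographically by (dx, dz).
.gridBest <- function(Sx, Sz, n, ox, oz) {
  M <- outer(2 * ox * Sx + n * ox^2, 2 * oz * Sz + n * oz^2, "+")
  m <- min(M)
  cand <- which(M <= m + 1e-12 * max(1, abs(m)), arr.ind = TRUE)
  dx <- ox[cand[, 1L]]; dz <- oz[cand[, 2L]]
  sel <- order(dx^2 + dz^2, dx, dz)[1L]
  c(dx[sel], dz[sel])
}

.sagittalShiftSearch <- function(d, coarseRange, coarseStep,
                                 fineRange, fineStep) {
  n <- nrow(d)
  Sx <- sum(d[, 1L]); Sz <- sum(d[, 3L])
  coarse <- .gridBest(Sx, Sz, n,
                      seq(-coarseRange, coarseRange, by = coarseStep),
                      seq(-coarseRange, coarseRange, by = coarseStep))
  .gridBest(Sx, Sz, n,
            coarse[1L] + seq(-fineRange, fineRange, by = fineStep),
            coarse[2L] + seq(-fineRange, fineRange, by = fineStep))
}

#' Align a cohort of spinal trajectories by iterative sagittal translation
#'
#' Repeats until convergence: compute the per-label average position over
#' the current trajectories; for each trajectory, find the sagittal-plane
#' translation (dx, dz) minimizing the sum of squared Euclidean distances
#' of its shared-label reference points to those averages by a two-stage
#' grid search (coarse then fine), and apply it.  Convergence is declared
#' when the largest applied translation drops below \code{tol}.  Only
#' labels present in at least two trajectories participate (scan coverage
#' of the spine varies with animal placement).  The objective is checked
#' to be non-increasing across iterations at run time.
#'
#' @param trajs list of \linkS4class{SpineTrajectory}.
#' @param coarseRange,coarseStep coarse grid half-range and step (mm);
#'   defaults 5 and 0.25.
#' @param fineRange,fineStep fine grid half-range and step (mm) around
#'   the coarse optimum; defaults 0.25 and 0.01.
#' @param tol convergence threshold on the largest applied translation
#'   (mm); default 1e-6 (1 um).
#' @param maxIter iteration cap.
#' @return a \linkS4class{CohortAlignment}.
#' @export
alignCohort <- function(trajs, coarseRange = 5, coarseStep = 0.25,
                        fineRange = 0.25, fineStep = 0.01,
                        tol = 1e-6, maxIter = 50L) {
  if (!length(trajs)) stop("empty cohort")
  if (length(trajs) == 1L) {
    mp <- .meanPointsOf(trajs)
    return(new("CohortAlignment", aligned = trajs, meanPoints = mp,
               iterations = 1L,
               finalObjective = 0, objectiveTrace = 0, converged = TRUE))
  }
  ordsList <- lapply(trajs, slot, "ordinals")
  shared <- as.integer(names(which(table(unlist(ordsList)) >= 2L)))
  if (length(shared) < 3L)
    stop("cohort alignment needs >= 3 vertebral labels shared by >= 2 ",
         "trajectories; found ", length(shared))
  trace <- numeric(0)
  it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    means <- .labelMeans(trajs, shared)
    maxShift <- 0
    for (k in seq_along(trajs)) {
      idx <- which(ordsList[[k]] %in% shared)
      if (!length(idx)) next
      mrows <- match(ordsList[[k]][idx], shared)
      d <- trajs[[k]]@points[idx, , drop = FALSE] -
        means[mrows, , drop = FALSE]
      sh <- .sagittalShiftSearch(d, coarseRange, coarseStep,
                                 fineRange, fineStep)
      trajs[[k]] <- .translate(trajs[[k]], dx = sh[1L], dz = sh[2L])
      maxShift <- max(maxShift, sqrt(sum(sh^2)))
    }
    means <- .labelMeans(trajs, shared)
    obj <- 0
    for (k in seq_along(trajs)) {
      idx <- which(ordsList[[k]] %in% shared)
      mrows <- match(ordsList[[k]][idx], shared)
      obj <- obj + sum((trajs[[k]]@points[idx, , drop = FALSE] -
                          means[mrows, , drop = FALSE])^2)
    }
    if (length(trace) && obj > trace[length(trace)] +
          1e-9 * max(1, trace[length(trace)]))
      stop("internal error: alignment objective increased (",
           trace[length(trace)], " -> ", obj, ")")
    trace <- c(trace, obj)
    if (maxShift < tol) { converged <- TRUE; break }
  }
  new("CohortAlignment", aligned = trajs,
      meanPoints = .meanPointsOf(trajs),
      iterations = it, finalObjective = trace[length(trace)],
      objectiveTrace = trace, converged = converged)
}

.labelMeans <- function(trajs, sharedOrds) {
  acc <- matrix(0, length(sharedOrds), 3L)
  cnt <- integer(length(sharedOrds))
  for (tr in trajs) {
    idx <- which(tr@ordinals %in% sharedOrds)
    rows <- match(tr@ordinals[idx], sharedOrds)
    acc[rows, ] <- acc[rows, ] + tr@points[idx, , drop = FALSE]
    cnt[rows] <- cnt[rows] + 1L
  }
  acc / cnt
}

.meanPointsOf <- function(trajs, formula = mouseVertebralFormula) {
  ords <- sort(unique(unlist(lapply(trajs, slot, "ordinals"))),
               decreasing = TRUE)
  stat <- lapply(ords, function(o) {
    pts <- do.call(rbind, lapply(trajs, function(tr) {
      i <- match(o, tr@ordinals)
      if (is.na(i)) NULL else tr@points[i, , drop = FALSE]
    }))
    n <- nrow(pts)
    c(colMeans(pts),
      if (n > 1L) apply(pts, 2L, stats::sd) else rep(NA_real_, 3L), n)
  })
  stat <- do.call(rbind, stat)
  data.frame(label = vertebraLabel(ords, formula), ordinal = ords,
             x_mm = stat[, 1L], y_mm = stat[, 2L], z_mm = stat[, 3L],
             sd_x = stat[, 4L], sd_y = stat[, 5L], sd_z = stat[, 6L],
             n = as.integer(stat[, 7L]))
}

#' Per-label mean trajectory with SD
#'
#' Arithmetic mean position and per-coordinate sample SD at every
#' vertebral label, over the trajectories containing that label (SD is NA
#' where only one trajectory covers a label).
#'
#' @param alignment a \linkS4class{CohortAlignment}.
#' @return data.frame (label, ordinal, x_mm, y_mm, z_mm, sd_x, sd_y,
#'   sd_z, n), posterior to anterior.
#' @export
meanTrajectory <- function(alignment) alignment@meanPoints
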