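#' @include AllClasses.R
NULL

#' Fit the spinal midline as a natural cubic spline
#'
#' Interpolates annotated horizontal-plane midline points (x
#' antero-posterior, y medio-lateral, both mm) with a natural cubic
#' spline: exact at the knots, C2 in between, zero second derivative at
#' the ends.  The midline must be a function of x (x-monotone), which
#' holds for prone animals; points are re-sorted by x and duplicate x
#' values are rejected.
#'
#' @param points two-column matrix or data.frame of (x_mm, y_mm), or a
#'   numeric x vector if \code{y} is given separately.
#' @param y optional numeric y values matching \code{points} as x.
#' @return a \linkS4class{MidlineSpline}.
#' @examples
#' sp <- fitMidline(cbind(c(0, 10, 20), c(0, 2, -1)))
#' evalMidline(sp, 10)   # exactly 2 at a knot
#' @export
fitMidline <- function(points, y = NULL) {
  if (!is.null(y)) points <- cbind(as.numeric(points), as.numeric(y))
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("midline points must have two columns (x_mm, y_mm)")
  if (nrow(points) < 2L)
    stop("at least 2 midline points are needed to fit a spline")
  if (anyNA(points) || any(!is.finite(points)))
    stop("midline points must be finite")
  ord <- order(points[, 1L])
  points <- points[ord, , drop = FALSE]
  if (any(diff(points[, 1L]) == 0))
    stop("duplicate x values in midline points; the midline must be ",
         "a function of the antero-posterior coordinate")
  f <- stats::splinefun(points[, 1L], points[, 2L], method = "natural")
  new("MidlineSpline", knots = unname(points), fun = f)
}

#' Evaluate a midline spline with endpoint clamping
#'
#' Evaluates y = f(x); x values outside the knot domain return the
#' nearest-endpoint spline value (constant extrapolation), matching the
#' stripe-projection convention.
#'
#' @param spline a \linkS4class{MidlineSpline}.
#' @param x numeric vector of antero-posterior positions (mm).
#' @return numeric vector of medio-lateral positions (mm).
#' @export
evalMidline <- function(spline, x) {
  k <- spline@knots
  spline@fun(pmin(pmax(x, k[1L, 1L]), k[nrow(k), 1L]))
}

#' Lift lateral-plane reference points to 3D using the midline spline
#'
#' Reference points are annotated on the lateral projection with only
#' their antero-posterior (x) and dorso-ventral (z) coordinates; their
#' medio-lateral (y) coordinate is interpolated from the midline spline,
#' yielding full 3D positions.
#'
#' @param lateralPoints two-column matrix or data.frame of (x_mm, z_mm).
#' @param spline a \linkS4class{MidlineSpline}.
#' @return numeric matrix n x 3 with columns x, y, z (mm).
#' @export
liftPoints <- function(lateralPoints, spline) {
  lp <- as.matrix(lateralPoints)
  if (ncol(lp) != 2L)
    stop("lateral points must have two columns (x_mm, z_mm)")
  if (anyNA(lp) || any(!is.finite(lp)))
    stop("lateral points must be finite")
  out <- cbind(x = lp[, 1L], y = evalMidline(spline, lp[, 1L]),
               z = lp[, 2L])
  unname(out)
}
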