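#' Construct a postprandial time grid
#'
#' A grid is the common set of time points (minutes since the meal) on which
#' every postprandial curve is observed. The default grid covers the six-hour
#' window after a meal at the 5-minute CGM cadence: 0, 5, ..., 360 minutes
#' (73 points).
#'
#' @param start First time point, minutes since meal.
#' @param end Last time point, minutes since meal.
#' @param step Spacing in minutes; must divide `end - start` exactly.
#' @return An object of class `cgm_grid`: a list with `points` (numeric
#'   vector) and `step`.
#' @examples
#' g <- make_grid()
#' length(g$points) # 73
#' @export
make_grid <- function(start = 0, end = 360, step = 5) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(step))
  if (step <= 0) stop("`step` must be positive.", call. = FALSE)
  if (end <= start) stop("`end` must exceed `start`.", call. = FALSE)
  k <- (end - start) / step
  if (abs(k - round(k)) > 1e-8) {
    stop("`end - start` (", end - start, ") is not an exact multiple of `step` (",
         step, ").", call. = FALSE)
  }
  structure(
    list(points = seq(start, end, by = step), step = step),
    class = "cgm_grid"
  )
}

#' @export
print.cgm_grid <- function(x, ...) {
  cat("<cgm_grid> ", length(x$points), " points on [",
      min(x$points), ", ", max(x$points), "] min, step ", x$step, " min\n",
      sep = "")
  invisible(x)
}

#' Trapezoidal quadrature weights for a grid
#'
#' Weights `w(t)` such that `sum(w * f)` equals the trapezoidal-rule
#' approximation of the integral of `f` over the grid's range. On the default
#' grid the weights sum to 360.
#'
#' @param grid A `cgm_grid`.
#' @return Numeric vector of weights, one per grid point.
#' @export
trapezoid_weights <- function(grid) {
  pts <- if (inherits(grid, "cgm_grid")) grid$points else as.numeric(grid)
  m <- length(pts)
  if (m < 2) stop("Quadrature needs at least two grid points.", call. = FALSE)
  d <- diff(pts)
  w <- numeric(m)
  w[1] <- d[1] / 2
  w[m] <- d[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (d[-length(d)] + d[-1]) / 2
  w
}

#' Quadrature inner product of functions sampled on a grid
#'
#' @param f,g Numeric vectors sampled on `grid`.
#' @param grid A `cgm_grid`.
#' @return Scalar `integral f(t) g(t) dt` by the trapezoidal rule.
#' @export
quad_inner <- function(f, g, grid) {
  w <- trapezoid_weights(grid)
  stopifnot(length(f) == length(w), length(g) == length(w))
  sum(w * f * g)
}

grid_points <- function(grid) {
  if (inherits(grid, "cgm_grid")) grid$points else as.numeric(grid)
}

same_grid <- function(a, b, tol = 1e-8) {
  pa <- grid_points(a); pb <- grid_points(b)
  length(pa) == length(pb) && max(abs(pa - pb)) <= tol
}
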