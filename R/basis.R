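#' Orthonormalize functions under trapezoidal quadrature
#'
#' Gram-Schmidt orthonormalization of the columns of `mat` with respect to the
#' inner product `<f, g> = integral f g dt` approximated on `grid`. Columns
#' that are (numerically) linearly dependent on earlier ones are rejected.
#'
#' @param mat Numeric matrix, one column per function sampled on `grid`.
#' @param grid A `cgm_grid`.
#' @param tol Dependence tolerance on the residual norm.
#' @return Matrix of the same shape with quadrature-orthonormal columns.
#' @export
orthonormalize <- function(mat, grid, tol = 1e-10) {
  mat <- as.matrix(mat)
  w <- trapezoid_weights(grid)
  stopifnot(nrow(mat) == length(w))
  out <- mat
  for (k in seq_len(ncol(mat))) {
    v <- mat[, k]
    if (k > 1) {
      prev <- out[, seq_len(k - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, w * v)
    }
    nrm <- sqrt(sum(w * v^2))
    if (nrm < tol) {
      stop("Column ", k, " is linearly dependent on earlier columns.",
           call. = FALSE)
    }
    out[, k] <- v / nrm
  }
  out
}

# Raw (pre-orthonormalization) eigenfunction shapes. The first mode is an
# almost level offset with a shallow concave bump near 100 min (overall
# postprandial level), the second a pronounced peak near 60-80 min (peak
# height), the third an early-vs-late peak contrast (peak timing).
fpc_shape_library <- function(t) {
  cbind(
    level  = 1 + 0.25 * exp(-0.5 * ((t - 100) / 110)^2),
    peak   = exp(-0.5 * ((t - 70) / 55)^2),
    timing = exp(-0.5 * ((t - 110) / 45)^2) - exp(-0.5 * ((t - 55) / 45)^2)
  )
}

#' Default orthonormal eigenfunction set
#'
#' Evaluates the package's built-in library of postprandial variation shapes
#' on `grid` and orthonormalizes them under trapezoidal quadrature. The three
#' shapes emulate the modes typically seen in postprandial CGM curves: an
#' overall-level mode, a peak-height mode around 60-80 minutes, and a
#' peak-timing contrast.
#'
#' @param grid A `cgm_grid`.
#' @param k Number of eigenfunctions (1 to 3).
#' @return Matrix `length(grid$points) x k`, quadrature-orthonormal columns.
#' @export
default_eigenfunctions <- function(grid, k = 3) {
  stopifnot(k >= 1, k <= 3)
  t <- grid_points(grid)
  raw <- fpc_shape_library(t)[, seq_len(k), drop = FALSE]
  orthonormalize(raw, grid)
}

# Apply the reproducible sign convention: the grid point with largest
# absolute value is positive.
apply_sign_convention <- function(mat) {
  for (k in seq_len(ncol(mat))) {
    v <- mat[, k]
    i <- which.max(abs(v))
    if (v[i] < 0) mat[, k] <- -v
  }
  mat
}
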