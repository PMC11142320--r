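#' Pointwise functional R-squared
#'
#' At each grid point `t` the standard univariate coefficient of
#' determination is computed across all curves:
#' `R2(t) = 1 - SSE(t)/SST(t)`, where `SSE(t)` sums squared differences
#' between observed and fitted values over every (subject, meal) pair and
#' `SST(t)` sums squared deviations of the observed values from their
#' cross-curve mean. Values may be negative (fitted worse than the mean);
#' grid points where all observed values coincide (zero total sum of
#' squares) are undefined and returned as `NA` with a warning.
#'
#' @param observed,fitted Matrices of identical shape (rows = curves), or
#'   [ppg_data()] objects for `observed`.
#' @return Numeric vector `R2(t)`, one value per grid point.
#' @export
pointwise_r2 <- function(observed, fitted) {
  if (inherits(observed, "ppg_data")) observed <- observed$Y
  if (inherits(fitted, "ppg_data")) fitted <- fitted$Y
  observed <- as.matrix(observed); fitted <- as.matrix(fitted)
  if (!identical(dim(observed), dim(fitted))) {
    stop("`observed` and `fitted` must have identical shape.", call. = FALSE)
  }
  if (nrow(observed) < 2) stop("Need at least 2 curves.", call. = FALSE)
  ybar <- colMeans(observed)
  sse <- colSums((observed - fitted)^2)
  sst <- colSums(sweep(observed, 2, ybar)^2)
  out <- 1 - sse / sst
  zero <- sst <= 0
  if (any(zero)) {
    warning(sum(zero), " grid point(s) have zero total sum of squares; ",
            "R2 undefined (NA) there.")
    out[zero] <- NA_real_
  }
  out
}

#' Global functional R-squared by trapezoidal quadrature
#'
#' Integrates the pointwise curve over the grid's range with trapezoidal
#' weights and normalizes by the range length, so a constant pointwise
#' curve returns its own value and the rule is exact for piecewise-linear
#' curves. Undefined (`NA`) points are excluded with renormalized weights.
#'
#' @param pointwise Numeric vector of pointwise values on `grid`.
#' @param grid A `cgm_grid`.
#' @return Scalar global value.
#' @export
global_r2 <- function(pointwise, grid) {
  pts <- grid_points(grid)
  if (length(pts) < 2) {
    stop("Global R2 needs at least two grid points.", call. = FALSE)
  }
  stopifnot(length(pointwise) == length(pts))
  w <- trapezoid_weights(grid)
  ok <- is.finite(pointwise)
  if (!any(ok)) stop("No finite pointwise values.", call. = FALSE)
  sum(w[ok] * pointwise[ok]) / sum(w[ok])
}

new_fr2_result <- function(pointwise, grid, variant) {
  structure(
    list(
      grid = grid,
      pointwise = pointwise,
      weights = trapezoid_weights(grid),
      global = global_r2(pointwise, grid),
      variant = variant
    ),
    class = "fr2_result"
  )
}

#' @export
print.fr2_result <- function(x, ...) {
  cat("<fr2_result> variant '", x$variant, "': global R2 = ",
      sprintf("%.4f", x$global), "\n", sep = "")
  invisible(x)
}

#' Variance explained by a two-level functional decomposition
#'
#' Computes pointwise and global R-squared for the participant-level
#' reconstruction (`mu + nu_j + sum_k a_ik phi_k`) and the full
#' reconstruction (adding the meal-level expansion).
#'
#' @param model An `mfpca_fit` fitted on `data`.
#' @param data The [ppg_data()] the model was fitted on.
#' @return List with two `fr2_result`s: `participant` and `full`.
#' @export
mfpca_r2 <- function(model, data) {
  if (!same_grid(model$grid, data$grid)) {
    stop("Model and data grids differ.", call. = FALSE)
  }
  if (nrow(model$scores_meal) != nrow(data$Y)) {
    stop("Model was not fitted on this dataset (row mismatch).",
         call. = FALSE)
  }
  list(
    participant = new_fr2_result(
      pointwise_r2(data$Y, reconstruct(model, "participant")),
      data$grid, "mfpca_participant"),
    full = new_fr2_result(
      pointwise_r2(data$Y, reconstruct(model, "full")),
      data$grid, "mfpca_full")
  )
}

#' Marginal and conditional R-squared for a function-on-scalar regression
#'
#' The marginal variant measures the variance explained by the fixed part
#' `X beta(t)` alone; the conditional variant adds the subject
#' random-effect functions `alpha_i(t)`.
#'
#' @param model A `fosr_fit`.
#' @param data The [ppg_data()] the model was fitted on.
#' @param covariates Covariate tibble aligned to `data` rows (defaults to
#'   the training design).
#' @return List with two `fr2_result`s: `marginal` and `conditional`.
#' @export
fosr_r2 <- function(model, data = NULL, covariates = NULL) {
  Y <- if (is.null(data)) model$Y else data$Y
  marg <- predict(model, covariates, mode = "marginal")
  cond <- predict(model, covariates, mode = "conditional")
  list(
    marginal = new_fr2_result(pointwise_r2(Y, marg), model$grid,
                              "fosr_marginal"),
    conditional = new_fr2_result(pointwise_r2(Y, cond), model$grid,
                                 "fosr_conditional")
  )
}

#' Choose the number of components by explained variability
#'
#' Refits the two-level decomposition at `K = H = 1, ..., max_K` (reusing
#' the mean and covariance estimates, which do not depend on the
#' truncation; scores are re-predicted at each truncation) and reports the
#' global full-model R-squared per truncation. The resulting table is
#' non-decreasing in `K = H` up to numerical tolerance and typically shows
#' an elbow at the generative rank.
#'
#' @param data A [ppg_data()].
#' @param max_K Largest truncation to evaluate.
#' @param include_day_effects Passed to [fit_mfpca()].
#' @param scores Score estimator.
#' @return Tibble with columns `K` and `r2_full`.
#' @export
select_components_by_r2 <- function(data, max_K = 5,
                                    include_day_effects = FALSE,
                                    scores = c("blup", "projection")) {
  scores <- match.arg(scores)
  stopifnot(max_K >= 1)
  mn <- estimate_mean_functions(data, include_day_effects)
  cv <- estimate_covariances(data, mn$mu, mn$nu)
  eb <- eigendecompose(cv$K_between, data$grid, max_K)
  ew <- eigendecompose(cv$K_within, data$grid, max_K)
  r2 <- numeric(max_K)
  for (k in seq_len(max_K)) {
    sc <- estimate_scores(data, mn$mu, mn$nu,
                          eb$functions[, seq_len(k), drop = FALSE],
                          eb$values[seq_len(k)],
                          ew$functions[, seq_len(k), drop = FALSE],
                          ew$values[seq_len(k)],
                          noise_var = cv$noise_var, method = scores)
    m <- length(data$grid$points)
    imap <- match(data$index$subject_id, rownames(sc$scores_subject))
    fitted <- matrix(mn$mu, nrow(data$Y), m, byrow = TRUE) +
      mn$nu[data$index$meal, , drop = FALSE] +
      (sc$scores_subject %*% t(eb$functions[, seq_len(k), drop = FALSE]))[imap, , drop = FALSE] +
      sc$scores_meal %*% t(ew$functions[, seq_len(k), drop = FALSE])
    r2[k] <- global_r2(pointwise_r2(data$Y, fitted), data$grid)
  }
  tibble::tibble(K = seq_len(max_K), r2_full = r2)
}
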