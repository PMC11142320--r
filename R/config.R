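#' Default postprandial mean function
#'
#' Smooth mean glucose trajectory: fasting-like level near 100 mg/dL rising
#' to roughly 140 mg/dL around 60 minutes post-meal and relaxing back over
#' the six-hour window.
#'
#' @param t Minutes since meal.
#' @return Glucose, mg/dL.
#' @export
default_mean_function <- function(t) {
  100 + 40 * (t / 60) * exp(1 - t / 60)
}

#' Generative configuration for the two-level curve simulator
#'
#' Bundles everything the simulator needs: grid, mean structure, the two
#' orthonormal eigenfunction sets with their eigenvalues (subject level
#' `lambda`, meal level `gamma`), measurement noise, covariate marginals and
#' coefficient functions for the regression simulator, and the law of the
#' subject random-effect function. Defaults encode the study conditions the
#' package is calibrated to: n = 150 subjects with 4 dinners each, a 33:67
#' subject:meal split of process variance, three eigenfunctions per level,
#' and 2 mg/dL white measurement noise.
#'
#' @param n_subjects Number of subjects `n`.
#' @param meals_per_subject Scalar or length-`n` vector of per-subject meal
#'   counts `J_i`.
#' @param grid A `cgm_grid`.
#' @param mean_function Function of `t` giving the global mean, mg/dL.
#' @param day_effects Optional matrix (`max(J) x length(grid)`) of day-shift
#'   functions summing to zero at each grid point; `NULL` means no day shift.
#' @param subject_eigenfunctions,meal_eigenfunctions Matrices with
#'   quadrature-orthonormal columns.
#' @param subject_eigenvalues,meal_eigenvalues Non-negative, non-increasing
#'   score variances on the integrated scale, (mg/dL)^2 x min (the
#'   eigenfunctions are unit-norm under quadrature over the 360-min
#'   window, so an eigenvalue of 144000 corresponds to about 400 (mg/dL)^2
#'   of pointwise variance).
#' @param noise_sd White measurement noise sd, mg/dL.
#' @param covariate_spec Named list of generator functions `function(n)` for
#'   meal- or subject-level covariates; see [default_covariate_spec()].
#' @param beta_functions Named list of coefficient functions of `t`; see
#'   [default_beta_functions()].
#' @param random_effect_sd Marginal sd of the subject random-effect function
#'   `alpha_i(t)`, mg/dL.
#' @param random_effect_lengthscale Squared-exponential length-scale of
#'   `alpha_i(t)`, minutes.
#' @param seed Integer root seed; every draw is a deterministic function of
#'   it.
#' @return A validated list of class `cgm_config`.
#' @export
generative_config <- function(n_subjects = 150,
                              meals_per_subject = 4,
                              grid = make_grid(),
                              mean_function = default_mean_function,
                              day_effects = NULL,
                              subject_eigenfunctions = default_eigenfunctions(grid, 3),
                              subject_eigenvalues = 0.33 * 144000 * c(0.6, 0.3, 0.1),
                              meal_eigenfunctions = default_eigenfunctions(grid, 3),
                              meal_eigenvalues = 0.67 * 144000 * c(0.6, 0.3, 0.1),
                              noise_sd = 2,
                              covariate_spec = default_covariate_spec(),
                              beta_functions = default_beta_functions(),
                              random_effect_sd = 10,
                              random_effect_lengthscale = 60,
                              seed = 1L) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      meals_per_subject = meals_per_subject,
      grid = grid,
      mean_function = mean_function,
      day_effects = day_effects,
      subject_eigenfunctions = as.matrix(subject_eigenfunctions),
      subject_eigenvalues = as.numeric(subject_eigenvalues),
      meal_eigenfunctions = as.matrix(meal_eigenfunctions),
      meal_eigenvalues = as.numeric(meal_eigenvalues),
      noise_sd = noise_sd,
      covariate_spec = covariate_spec,
      beta_functions = beta_functions,
      random_effect_sd = random_effect_sd,
      random_effect_lengthscale = random_effect_lengthscale,
      seed = as.integer(seed)
    ),
    class = "cgm_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg$grid, "cgm_grid"))
  if (cfg$n_subjects < 1) stop("Need at least one subject.", call. = FALSE)
  J <- meal_counts(cfg)
  if (any(J < 1)) stop("Every subject needs at least one meal.", call. = FALSE)
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  check_eigensystem(cfg$subject_eigenfunctions, cfg$subject_eigenvalues,
                    cfg$grid, "subject")
  check_eigensystem(cfg$meal_eigenfunctions, cfg$meal_eigenvalues,
                    cfg$grid, "meal")
  if (!is.null(cfg$day_effects)) {
    nu <- as.matrix(cfg$day_effects)
    if (ncol(nu) != length(cfg$grid$points)) {
      stop("`day_effects` must have one column per grid point.", call. = FALSE)
    }
    if (max(abs(colSums(nu))) > 1e-8) {
      stop("`day_effects` must sum to zero at every grid point.", call. = FALSE)
    }
  }
  invisible(cfg)
}

check_eigensystem <- function(phi, lambda, grid, label) {
  if (ncol(phi) != length(lambda)) {
    stop("Mismatched ", label, " eigenfunction/eigenvalue lengths (",
         ncol(phi), " vs ", length(lambda), ").", call. = FALSE)
  }
  if (any(lambda < 0)) stop(label, " eigenvalues must be >= 0.", call. = FALSE)
  if (is.unsorted(rev(lambda))) {
    stop(label, " eigenvalues must be non-increasing.", call. = FALSE)
  }
  w <- trapezoid_weights(grid)
  G <- crossprod(phi, w * phi)
  if (max(abs(G - diag(ncol(phi)))) > 1e-8) {
    stop(label, " eigenfunctions are not quadrature-orthonormal (tol 1e-8).",
         call. = FALSE)
  }
  invisible(TRUE)
}

meal_counts <- function(cfg) {
  J <- cfg$meals_per_subject
  if (length(J) == 1) J <- rep(J, cfg$n_subjects)
  if (length(J) != cfg$n_subjects) {
    stop("`meals_per_subject` must be scalar or length n.", call. = FALSE)
  }
  as.integer(J)
}

#' Default covariate marginal distributions
#'
#' Independent draws emulating the marginal distributions of a
#' middle-aged European cohort's dinner records: age ~ 46 (14) yrs, weight
#' ~ 75 (15) kg, 37% male, HbA1c ~ 5.35 (0.30) %, carbohydrates ~ 59.9
#' (40.5) g, fats ~ 30.1 (23.8) g, proteins ~ 27.5 (17.9) g and fiber ~ 8.8
#' (6.7) g (nutrients truncated at zero). Subject-level entries are marked so
#' the simulator holds them fixed across a subject's meals.
#'
#' @return Named list; each element is `list(draw = function(m), level)`
#'   with `level` either `"subject"` or `"meal"`.
#' @export
default_covariate_spec <- function() {
  list(
    age = list(draw = function(m) round(pmin(pmax(stats::rnorm(m, 46, 14), 18), 85), 1),
               level = "subject"),
    weight = list(draw = function(m) round(pmin(pmax(stats::rnorm(m, 75, 15), 40), 145), 1),
                  level = "subject"),
    gender_male = list(draw = function(m) stats::rbinom(m, 1, 0.37),
                       level = "subject"),
    hba1c = list(draw = function(m) round(pmin(pmax(stats::rnorm(m, 5.35, 0.3), 4.2), 6.4), 2),
                 level = "subject"),
    carbohydrates = list(draw = function(m) round(pmax(stats::rnorm(m, 59.9, 40.5), 0), 1),
                         level = "meal"),
    fats = list(draw = function(m) round(pmax(stats::rnorm(m, 30.1, 23.8), 0), 1),
                level = "meal"),
    proteins = list(draw = function(m) round(pmax(stats::rnorm(m, 27.5, 17.9), 0), 1),
                    level = "meal"),
    fiber = list(draw = function(m) round(pmax(stats::rnorm(m, 8.8, 6.7), 0), 1),
                 level = "meal")
  )
}

#' Default coefficient functions for the regression simulator
#'
#' A compact design used throughout the recovery tests: intercept (the
#' default mean trajectory), an age effect peaking near 90 minutes, a
#' carbohydrate effect tracking the postprandial rise, an early fat-induced
#' blunting followed by a mild late rise, and a fiber effect switching on
#' after about 90 minutes. Units are mg/dL per covariate unit.
#'
#' @return Named list of functions of `t` (minutes).
#' @export
default_beta_functions <- function() {
  list(
    intercept = default_mean_function,
    age = function(t) 0.15 * exp(-0.5 * ((t - 90) / 60)^2),
    carbohydrates = function(t) 0.35 * (t / 60) * exp(1 - t / 60),
    fats = function(t) -0.15 * exp(-0.5 * ((t - 35) / 25)^2) +
      0.06 * exp(-0.5 * ((t - 180) / 80)^2),
    fiber = function(t) -0.25 * stats::plogis((t - 90) / 20)
  )
}

# Deterministic substream seed derivation: one root seed, fixed offsets per
# component, so e.g. adding meals does not perturb subject-level draws.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 2029 + offset) %% 2147483629L
}
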