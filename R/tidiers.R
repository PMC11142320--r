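#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy eigenfunctions of a two-level decomposition
#'
#' @param x An `mfpca_fit`.
#' @param ... Unused.
#' @return Tibble with `level` (subject/meal), `component`, `t`, `value`
#'   and the component's `eigenvalue`.
#' @export
tidy.mfpca_fit <- function(x, ...) {
  t <- x$grid$points
  m <- length(t)
  K <- ncol(x$phi); H <- ncol(x$psi)
  tibble::tibble(
    level = c(rep("subject", K * m), rep("meal", H * m)),
    component = c(rep(seq_len(K), each = m), rep(seq_len(H), each = m)),
    t = rep(t, K + H),
    value = c(as.vector(x$phi), as.vector(x$psi)),
    eigenvalue = c(rep(x$lambda, each = m), rep(x$gamma, each = m))
  )
}

#' One-row summary of a two-level decomposition
#'
#' @param x An `mfpca_fit`.
#' @param ... Unused.
#' @return Tibble with truncations, eigenvalue sums, subject variance
#'   share and the noise variance.
#' @export
glance.mfpca_fit <- function(x, ...) {
  vp <- variance_proportions(x)
  tibble::tibble(
    K = ncol(x$phi), H = ncol(x$psi),
    lambda_sum = sum(x$lambda), gamma_sum = sum(x$gamma),
    subject_share = vp$share[vp$level == "subject"],
    noise_var = x$noise_var,
    n_subjects = length(x$J), n_curves = nrow(x$scores_meal)
  )
}

#' Tidy coefficient functions of a function-on-scalar regression
#'
#' @param x A `fosr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (term, t): estimate, standard error and
#'   (when bands were computed) pointwise and joint limits.
#' @export
tidy.fosr_fit <- function(x, ...) {
  if (!is.null(x$bands)) return(x$bands)
  m <- length(x$grid$points)
  tibble::tibble(
    term = rep(x$terms, each = m),
    t = rep(x$grid$points, length(x$terms)),
    estimate = as.vector(t(x$beta)),
    se = as.vector(t(x$beta_se))
  )
}

#' One-row summary of a function-on-scalar regression
#'
#' @param x A `fosr_fit`.
#' @param ... Unused.
#' @return Tibble with stratum, sizes, mean variance components and the
#'   in-sample marginal/conditional global R-squared.
#' @export
glance.fosr_fit <- function(x, ...) {
  r2 <- fosr_r2(x)
  tibble::tibble(
    stratum = x$stratum,
    n_subjects = nlevels(x$subject),
    n_curves = nrow(x$Y),
    n_terms = length(x$terms),
    mean_sigma2_eps = mean(x$sigma2_eps),
    mean_tau2 = mean(x$tau2),
    r2_marginal = r2$marginal$global,
    r2_conditional = r2$conditional$global
  )
}

#' Tidy a functional R-squared result
#'
#' @param x An `fr2_result`.
#' @param ... Unused.
#' @return Tibble with `t`, `r2` and the quadrature `weight` per point.
#' @export
tidy.fr2_result <- function(x, ...) {
  tibble::tibble(t = x$grid$points, r2 = x$pointwise, weight = x$weights)
}

#' One-row summary of a functional R-squared result
#'
#' @param x An `fr2_result`.
#' @param ... Unused.
#' @return Tibble with the variant label and the global value.
#' @export
glance.fr2_result <- function(x, ...) {
  tibble::tibble(variant = x$variant, r2_global = x$global)
}
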