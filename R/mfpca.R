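#' Estimate mean functions of the two-level model
#'
#' The global mean `mu(t)` is a penalized-spline smooth of the
#' cross-sectional mean curve. With `include_day_effects = TRUE` the
#' per-meal-ordinal deviations `nu_j(t)` are likewise smoothed and then
#' centered to satisfy the count-weighted sum-to-zero identifiability
#' constraint; with the flag off they are identically zero.
#'
#' @param data A [ppg_data()].
#' @param include_day_effects Estimate meal-ordinal shifts `nu_j(t)`?
#' @return List with `mu` (numeric vector) and `nu` (matrix, `max(J) x`
#'   grid length).
#' @export
estimate_mean_functions <- function(data, include_day_effects = FALSE) {
  if (nrow(data$Y) < 2) stop("Need at least 2 curves.", call. = FALSE)
  t <- data$grid$points
  mu <- smooth_curve(colMeans(data$Y), t)
  maxJ <- max(data$index$meal)
  nu <- matrix(0, maxJ, length(t))
  if (include_day_effects) {
    counts <- integer(maxJ)
    for (j in seq_len(maxJ)) {
      sel <- data$index$meal == j
      counts[j] <- sum(sel)
      if (counts[j] == 1) {
        warning("Meal ordinal ", j, " has a single curve; nu_", j,
                " shrunk to 0.")
        next
      }
      if (counts[j] >= 2) {
        dev <- colMeans(data$Y[sel, , drop = FALSE]) - mu
        nu[j, ] <- smooth_curve(dev, t)
      }
    }
    # count-weighted sum-to-zero constraint
    wbar <- colSums(counts * nu) / sum(counts)
    nu <- sweep(nu, 2, wbar)
  }
  list(mu = mu, nu = nu)
}

# Penalized-spline smooth of a curve observed on the grid; smoothing
# parameter by REML. Falls back to the raw curve for degenerate inputs.
smooth_curve <- function(y, t, k = NULL) {
  if (stats::sd(y) < 1e-12) return(rep(mean(y), length(y)))
  if (is.null(k)) k <- min(20L, length(t) - 2L)
  fit <- mgcv::gam(y ~ s(t, k = k, bs = "ps"), method = "REML")
  as.vector(stats::fitted(fit))
}

#' Method-of-moments covariance estimation for the two-level model
#'
#' Given fitted mean functions, forms the raw total covariance from
#' same-curve residual cross-products and the raw between-subject covariance
#' from within-subject, different-meal cross-products (pair counts
#' `sum_i J_i (J_i - 1)`). Both surfaces are smoothed with bivariate
#' penalized splines — the total surface off-diagonal, so the white-noise
#' nugget can be read off the diagonal: `sigma^2` is the average positive
#' excess of the raw total diagonal over the smoothed diagonal. The
#' within-subject surface is the difference of the smoothed surfaces.
#'
#' @param data A [ppg_data()].
#' @param mu,nu Mean components from [estimate_mean_functions()].
#' @param smooth Smooth the raw moment surfaces (default `TRUE`)?
#' @return List with matrices `K_total`, `K_between`, `K_within` (all
#'   symmetric) and scalar `noise_var`.
#' @export
estimate_covariances <- function(data, mu, nu = NULL, smooth = TRUE) {
  t <- data$grid$points
  m <- length(t)
  if (is.null(nu)) nu <- matrix(0, max(data$index$meal), m)
  R <- data$Y - matrix(mu, nrow(data$Y), m, byrow = TRUE) -
    nu[data$index$meal, , drop = FALSE]
  N <- nrow(R)
  H_total <- crossprod(R) / N

  rows_by_subj <- subject_rows(data)
  pair_count <- sum(vapply(rows_by_subj, function(r) {
    length(r) * (length(r) - 1)
  }, numeric(1)))
  if (pair_count == 0) {
    stop("No subject has 2+ meals: the between-subject covariance is ",
         "inestimable. Fit a single-level decomposition instead.",
         call. = FALSE)
  }
  H_between <- matrix(0, m, m)
  for (r in rows_by_subj) {
    if (length(r) < 2) next
    Ri <- R[r, , drop = FALSE]
    si <- colSums(Ri)
    H_between <- H_between + outer(si, si) - crossprod(Ri)
  }
  H_between <- H_between / pair_count
  H_between <- (H_between + t(H_between)) / 2

  if (smooth) {
    G_total <- smooth_surface(H_total, t, drop_diag = TRUE)
    K_between <- smooth_surface(H_between, t, drop_diag = FALSE)
    noise_var <- mean(pmax(diag(H_total) - diag(G_total), 0))
  } else {
    G_total <- H_total
    K_between <- H_between
    noise_var <- 0
  }
  K_within <- G_total - K_between
  list(
    K_total = G_total,
    K_between = K_between,
    K_within = (K_within + t(K_within)) / 2,
    noise_var = noise_var
  )
}

# Bivariate penalized-spline smooth of a covariance surface (tensor-product
# basis, REML smoothness selection), optionally excluding the diagonal so a
# white-noise nugget does not leak into the smooth. Result symmetrized.
smooth_surface <- function(K, t, drop_diag = TRUE, k = 10) {
  m <- length(t)
  df <- data.frame(
    value = as.vector(K),
    s = rep(t, times = m),
    u = rep(t, each = m)
  )
  if (drop_diag) df <- df[df$s != df$u, , drop = FALSE]
  fit <- mgcv::gam(value ~ te(s, u, k = c(k, k), bs = "ps"),
                   data = df, method = "REML")
  pred <- stats::predict(fit, newdata = data.frame(
    s = rep(t, times = m), u = rep(t, each = m)))
  G <- matrix(pred, m, m)
  (G + t(G)) / 2
}

#' Quadrature-weighted eigendecomposition of a covariance surface
#'
#' Solves the functional eigenproblem on the grid by symmetrizing with the
#' square-root trapezoidal weights. Negative eigenvalues are truncated to
#' zero; eigenfunctions are unit-norm under quadrature, ordered by
#' decreasing eigenvalue and signed so that the grid point of largest
#' absolute value is positive.
#'
#' @param K Symmetric covariance matrix on the grid.
#' @param grid A `cgm_grid`.
#' @param n_components Number of leading eigenpairs to return.
#' @return List with `functions` (matrix, one column per eigenfunction) and
#'   `values` (non-negative, non-increasing).
#' @export
eigendecompose <- function(K, grid, n_components) {
  m <- length(grid$points)
  if (n_components > m) {
    stop("Requested ", n_components, " components but the grid has only ",
         m, " points.", call. = FALSE)
  }
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("Covariance surface is not symmetric.", call. = FALSE)
  }
  w <- trapezoid_weights(grid)
  sw <- sqrt(w)
  A <- sw * t(sw * t(K)) # diag(sw) K diag(sw)
  ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- pmax(ee$values[seq_len(n_components)], 0)
  funs <- ee$vectors[, seq_len(n_components), drop = FALSE] / sw
  funs <- apply_sign_convention(funs)
  list(functions = funs, values = vals)
}

#' Score prediction for a fitted two-level decomposition
#'
#' Default estimator is the best linear unbiased predictor under joint
#' normality of scores and white noise: for each subject the stacked linear
#' system implied by the covariance of that subject's residual curves is
#' solved, jointly for the subject-level scores `a_ik` and all meal-level
#' scores `b_ijh`. The alternative `"projection"` estimator projects the
#' subject-mean residual on the subject-level eigenfunctions and the
#' remaining residual on the meal-level eigenfunctions under quadrature
#' (no shrinkage).
#'
#' @param data A [ppg_data()].
#' @param mu,nu Mean components.
#' @param phi,lambda Subject-level eigenfunctions (columns) and eigenvalues.
#' @param psi,gamma Meal-level eigenfunctions and eigenvalues.
#' @param noise_var White-noise variance `sigma^2`.
#' @param method `"blup"` or `"projection"`.
#' @return List with `scores_subject` (`n x K`, rownames = subject ids) and
#'   `scores_meal` (`sum(J) x H`, aligned to the dataset rows).
#' @export
estimate_scores <- function(data, mu, nu, phi, lambda, psi, gamma,
                            noise_var = 0,
                            method = c("blup", "projection")) {
  method <- match.arg(method)
  t <- data$grid$points
  m <- length(t)
  K <- ncol(phi); H <- ncol(psi)
  R <- data$Y - matrix(mu, nrow(data$Y), m, byrow = TRUE) -
    nu[data$index$meal, , drop = FALSE]
  rows_by_subj <- subject_rows(data)
  n <- length(rows_by_subj)
  a <- matrix(0, n, K, dimnames = list(names(rows_by_subj), NULL))
  b <- matrix(0, nrow(R), H)

  if (method == "projection") {
    w <- trapezoid_weights(data$grid)
    for (i in seq_along(rows_by_subj)) {
      r <- rows_by_subj[[i]]
      rbar <- colMeans(R[r, , drop = FALSE])
      a[i, ] <- crossprod(phi, w * rbar)
      Ui <- as.vector(phi %*% a[i, ])
      for (j in r) {
        b[j, ] <- crossprod(psi, w * (R[j, ] - Ui))
      }
    }
    return(list(scores_subject = a, scores_meal = b))
  }

  # BLUP: per subject solve (Z'Z + sigma^2 D^{-1}) xi = Z'R_stacked.
  # Components with (near-)zero variance get score 0 by the shrinkage limit.
  act_a <- lambda > 1e-12
  act_b <- gamma > 1e-12
  for (i in seq_along(rows_by_subj)) {
    r <- rows_by_subj[[i]]
    Ji <- length(r)
    Ka <- sum(act_a); Hb <- sum(act_b)
    p <- Ka + Ji * Hb
    if (p == 0) next
    Z <- matrix(0, Ji * m, p)
    if (Ka > 0) {
      Z[, seq_len(Ka)] <- do.call(rbind, replicate(Ji, list(
        phi[, act_a, drop = FALSE])))
    }
    if (Hb > 0) {
      for (jj in seq_len(Ji)) {
        Z[(jj - 1) * m + seq_len(m), Ka + (jj - 1) * Hb + seq_len(Hb)] <-
          psi[, act_b, drop = FALSE]
      }
    }
    dinv <- c(1 / lambda[act_a], rep(1 / gamma[act_b], Ji))
    rhs <- crossprod(Z, as.vector(t(R[r, , drop = FALSE])))
    Amat <- crossprod(Z) + max(noise_var, 0) * diag(dinv, p)
    xi <- tryCatch(solve(Amat, rhs), error = function(e) {
      warning("Singular score system for subject ", names(rows_by_subj)[i],
              "; ridge jitter applied.")
      solve(Amat + diag(1e-8, p), rhs)
    })
    if (Ka > 0) a[i, act_a] <- xi[seq_len(Ka)]
    if (Hb > 0) {
      for (jj in seq_len(Ji)) {
        b[r[jj], act_b] <- xi[Ka + (jj - 1) * Hb + seq_len(Hb)]
      }
    }
  }
  list(scores_subject = a, scores_meal = b)
}

#' Fit the two-level functional principal component decomposition
#'
#' Orchestrates mean estimation, method-of-moments covariance estimation
#' with bivariate smoothing, quadrature-weighted eigendecomposition at both
#' levels, and score prediction. Estimation is deterministic: refitting with
#' the same data and options reproduces the model exactly.
#'
#' @param data A [ppg_data()].
#' @param K,H Number of subject-/meal-level components (defaults 3 and 3).
#' @param include_day_effects Estimate meal-ordinal mean shifts?
#' @param scores Score estimator, `"blup"` (default) or `"projection"`.
#' @param smooth_covariance Smooth the moment surfaces?
#' @return Object of class `mfpca_fit`.
#' @export
fit_mfpca <- function(data, K = 3, H = 3, include_day_effects = FALSE,
                      scores = c("blup", "projection"),
                      smooth_covariance = TRUE) {
  scores <- match.arg(scores)
  stopifnot(K >= 1, H >= 1)
  mn <- estimate_mean_functions(data, include_day_effects)
  cv <- estimate_covariances(data, mn$mu, mn$nu, smooth = smooth_covariance)
  eb <- eigendecompose(cv$K_between, data$grid, K)
  ew <- eigendecompose(cv$K_within, data$grid, H)
  sc <- estimate_scores(data, mn$mu, mn$nu,
                        eb$functions, eb$values,
                        ew$functions, ew$values,
                        noise_var = cv$noise_var, method = scores)
  colnames(sc$scores_subject) <- paste0("a", seq_len(K))
  colnames(sc$scores_meal) <- paste0("b", seq_len(H))
  structure(
    list(
      grid = data$grid,
      index = data$index,
      J = data$J,
      mu = mn$mu,
      nu = mn$nu,
      include_day_effects = include_day_effects,
      phi = eb$functions, lambda = eb$values,
      psi = ew$functions, gamma = ew$values,
      scores_subject = sc$scores_subject,
      scores_meal = sc$scores_meal,
      noise_var = cv$noise_var,
      score_method = scores
    ),
    class = "mfpca_fit"
  )
}

#' @export
print.mfpca_fit <- function(x, ...) {
  vp <- variance_proportions(x)
  cat("<mfpca_fit> K =", ncol(x$phi), ", H =", ncol(x$psi),
      "| subject share", sprintf("%.3f", vp$share[vp$level == "subject"]),
      "| noise var", sprintf("%.2f", x$noise_var), "\n")
  invisible(x)
}

#' Reconstruct fitted curves from a two-level decomposition
#'
#' `"participant"` level returns `mu + nu_j + sum_k a_ik phi_k`; `"full"`
#' adds the meal-level expansion `sum_h b_ijh psi_h`.
#'
#' @param model An `mfpca_fit`.
#' @param level `"participant"` or `"full"`.
#' @return Matrix of fitted curves, rows aligned to the fitted dataset.
#' @export
reconstruct <- function(model, level = c("participant", "full")) {
  level <- match.arg(level)
  m <- length(model$grid$points)
  M <- nrow(model$scores_meal)
  base <- matrix(model$mu, M, m, byrow = TRUE) +
    model$nu[model$index$meal, , drop = FALSE]
  imap <- match(model$index$subject_id, rownames(model$scores_subject))
  fit <- base + (model$scores_subject %*% t(model$phi))[imap, , drop = FALSE]
  if (level == "full") {
    fit <- fit + model$scores_meal %*% t(model$psi)
  }
  fit
}

#' Hierarchical variance shares from the fitted eigenvalues
#'
#' The subject-level share is `sum(lambda) / (sum(lambda) + sum(gamma))`,
#' i.e. the proportion of the process variance captured by the model that
#' sits between subjects; the meal-level share is its complement.
#'
#' @param model An `mfpca_fit`.
#' @return Tibble with columns `level` and `share` (sums to 1).
#' @export
variance_proportions <- function(model) {
  tot <- sum(model$lambda) + sum(model$gamma)
  if (tot <= 0) {
    stop("All eigenvalues are zero; variance shares are undefined.",
         call. = FALSE)
  }
  tibble::tibble(
    level = c("subject", "meal"),
    share = c(sum(model$lambda), sum(model$gamma)) / tot
  )
}
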