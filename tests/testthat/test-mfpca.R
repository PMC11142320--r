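test_that("mean estimation handles degenerate and standard inputs", {
  g <- make_grid()
  # constant curves: mean is the constant, day effects vanish
  d <- new_ppg_data(matrix(107, 6, 73), rep(c("A", "B", "C"), each = 2),
                    rep(1:2, 3), g)
  mn <- estimate_mean_functions(d, include_day_effects = TRUE)
  expect_equal(mn$mu, rep(107, 73), tolerance = 1e-10)
  expect_lt(max(abs(mn$nu)), 1e-10)

  # flag off: day effects identically zero
  sim <- simulate_mfpca_data(tiny_config(seed = 71))
  mn2 <- estimate_mean_functions(sim$data, include_day_effects = FALSE)
  expect_equal(max(abs(mn2$nu)), 0)

  # recovery tolerance calibrated by simulation at the default scale
  sim3 <- simulate_mfpca_data(generative_config(seed = 72))
  mn3 <- estimate_mean_functions(sim3$data)
  expect_lt(max(abs(mn3$mu - sim3$truth$mu)), 4.5)

  # a meal ordinal with a single curve is shrunk to zero with a warning
  d2 <- ppg_subset(sim$data, 1:4) # ordinals 2 and 3 have one curve each
  expect_warning(estimate_mean_functions(d2, include_day_effects = TRUE),
                 "single curve")

  expect_error(estimate_mean_functions(ppg_subset(sim$data, 1)), "2 curves")
})

test_that("moment-based covariance separation recovers both levels", {
  # noiseless, no meal-level process: raw moment surfaces separate exactly
  cfg <- tiny_config(n = 20, J = 3, K = 2, H = 1, noise_sd = 0, seed = 81)
  cfg$meal_eigenvalues <- 0
  sim <- simulate_mfpca_data(cfg)
  mn <- estimate_mean_functions(sim$data)
  cv <- estimate_covariances(sim$data, mn$mu, mn$nu, smooth = FALSE)
  expect_lt(max(abs(cv$K_within)), 1e-6 * max(abs(cv$K_between)))

  # rank-1 subject level: smoothed K_between close to lambda * phi phi^T
  g <- make_grid()
  phi <- default_eigenfunctions(g, 2)
  cfg2 <- generative_config(
    n_subjects = 300, meals_per_subject = 4,
    subject_eigenfunctions = phi[, 1, drop = FALSE],
    subject_eigenvalues = 36000,
    meal_eigenfunctions = phi[, 2, drop = FALSE],
    meal_eigenvalues = 24000, noise_sd = 2, seed = 82)
  sim2 <- simulate_mfpca_data(cfg2)
  mn2 <- estimate_mean_functions(sim2$data)
  cv2 <- estimate_covariances(sim2$data, mn2$mu, mn2$nu)
  expect_lt(max(abs(cv2$K_between - 36000 * tcrossprod(phi[, 1]))), 10)

  # symmetry by construction
  expect_identical(cv2$K_between, t(cv2$K_between))

  # no repeat meals: between-level covariance inestimable
  d1 <- ppg_subset(sim$data, which(sim$data$index$meal == 1))
  expect_error(estimate_covariances(d1, mn$mu, mn$nu), "single-level")
})

test_that("quadrature eigendecomposition matches exact constructions", {
  g <- make_grid()
  phi <- default_eigenfunctions(g, 2)

  # rank-1: unit eigenvalue, eigenfunction recovered up to sign convention
  e1 <- eigendecompose(tcrossprod(phi[, 1]), g, 2)
  expect_equal(e1$values, c(1, 0), tolerance = 1e-10)
  expect_lt(min(max(abs(e1$functions[, 1] - phi[, 1])),
                max(abs(e1$functions[, 1] + phi[, 1]))), 1e-8)
  # sign convention: the largest-|value| grid point is positive
  expect_gt(e1$functions[which.max(abs(e1$functions[, 1])), 1], 0)

  # zero surface
  e0 <- eigendecompose(matrix(0, 73, 73), g, 3)
  expect_equal(e0$values, rep(0, 3))

  # two-component construction: eigenvalues (4, 1) and both functions
  K <- 4 * tcrossprod(phi[, 1]) + tcrossprod(phi[, 2])
  e2 <- eigendecompose(K, g, 2)
  expect_equal(e2$values, c(4, 1), tolerance = 1e-8)
  for (k in 1:2) {
    expect_lt(min(max(abs(e2$functions[, k] - phi[, k])),
                  max(abs(e2$functions[, k] + phi[, k]))), 1e-8)
  }

  expect_error(eigendecompose(K, g, 100), "only")
})

test_that("eigendecomposition agrees with a dense generalized eigensolver", {
  # independent oracle: the discretized operator K %*% diag(w) solved as a
  # plain (non-symmetric) eigenproblem
  g <- make_grid(0, 190, 10) # 20 points
  w <- trapezoid_weights(g)
  set.seed(99)
  for (rep in 1:10) {
    A <- matrix(stats::rnorm(400), 20, 20)
    K <- crossprod(A) / 20
    ours <- eigendecompose(K, g, 5)
    oracle <- sort(Re(eigen(K %*% diag(w))$values), decreasing = TRUE)
    expect_equal(ours$values, oracle[1:5], tolerance = 1e-8)
  }
})

test_that("score prediction is exact in the interpolation limit and shrinks", {
  g <- make_grid()
  phi <- default_eigenfunctions(g, 2)
  mu0 <- rep(0, 73)
  nu0 <- matrix(0, 1, 73)

  # noiseless single subject, single component each level, known scores
  Y <- matrix(3 * phi[, 1] + 1.5 * phi[, 2], 1, 73, byrow = TRUE)
  d <- new_ppg_data(Y, "S001", 1, g)
  sc <- estimate_scores(d, mu0, nu0, phi[, 1, drop = FALSE], 1,
                        phi[, 2, drop = FALSE], 1, noise_var = 0)
  expect_equal(as.numeric(sc$scores_subject[1, 1]), 3, tolerance = 1e-6)
  expect_equal(as.numeric(sc$scores_meal[1, 1]), 1.5, tolerance = 1e-6)

  # empirical mean of subject scores is near zero at CLT scale
  sim <- simulate_mfpca_data(tiny_config(n = 150, seed = 91))
  fit <- quiet_fit_mfpca(sim$data, K = 2, H = 2)
  for (k in 1:2) {
    expect_lt(abs(mean(fit$scores_subject[, k])),
              3 * sqrt(fit$lambda[k] / 150))
  }

  # heavy noise: BLUP shrinks relative to quadrature projection
  cfg <- tiny_config(n = 40, J = 3, K = 1, H = 1, seed = 92,
                     total_var = 150)
  cfg$noise_sd <- 10 * sqrt(cfg$subject_eigenvalues[1]) / 19
  simn <- simulate_mfpca_data(cfg)
  mn <- estimate_mean_functions(simn$data)
  args <- list(simn$data, mn$mu, mn$nu,
               cfg$subject_eigenfunctions, cfg$subject_eigenvalues,
               cfg$meal_eigenfunctions, cfg$meal_eigenvalues)
  bl <- do.call(estimate_scores, c(args, noise_var = cfg$noise_sd^2,
                                   method = "blup"))
  pr <- do.call(estimate_scores, c(args, method = "projection"))
  expect_lt(mean(abs(bl$scores_subject)), mean(abs(pr$scores_subject)))
})

test_that("full fits are deterministic with the documented defaults", {
  expect_equal(formals(fit_mfpca)$K, 3)
  expect_equal(formals(fit_mfpca)$H, 3)
  sim <- simulate_mfpca_data(tiny_config(seed = 101))
  f1 <- quiet_fit_mfpca(sim$data, K = 2, H = 2)
  f2 <- quiet_fit_mfpca(sim$data, K = 2, H = 2)
  expect_identical(f1[setdiff(names(f1), "call")],
                   f2[setdiff(names(f2), "call")])
})

test_that("rank-1 fits reduce residuals to the noise floor", {
  cfg <- tiny_config(n = 60, J = 3, K = 1, H = 1, noise_sd = 2, seed = 111)
  sim <- simulate_mfpca_data(cfg)
  fit <- quiet_fit_mfpca(sim$data, K = 1, H = 1)
  resid_sd <- stats::sd(sim$data$Y - reconstruct(fit, "full"))
  expect_lt(resid_sd, 1.5 * cfg$noise_sd)
  expect_gt(resid_sd, 0.5 * cfg$noise_sd)
})

test_that("reconstruction levels differ exactly by the meal-level expansion", {
  sim <- simulate_mfpca_data(tiny_config(seed = 121))
  fit <- quiet_fit_mfpca(sim$data, K = 2, H = 2)
  gap <- reconstruct(fit, "full") - reconstruct(fit, "participant")
  expect_equal(unname(gap), unname(fit$scores_meal %*% t(fit$psi)),
               tolerance = 1e-12)

  # zero scores: reconstruction is the mean structure alone
  fit0 <- fit
  fit0$scores_subject[] <- 0
  fit0$scores_meal[] <- 0
  rec0 <- reconstruct(fit0, "full")
  expect_equal(rec0[1, ], fit$mu, tolerance = 1e-12)

  expect_error(reconstruct(fit, "both"), "arg")
})

test_that("noiseless constructed data is reconstructed exactly", {
  # model built from the generative truth; scores estimated from the data
  cfg <- tiny_config(n = 8, J = 2, K = 1, H = 1, noise_sd = 0, seed = 131)
  sim <- simulate_mfpca_data(cfg)
  sc <- estimate_scores(sim$data, sim$truth$mu, sim$truth$nu,
                        sim$truth$phi, sim$truth$lambda,
                        sim$truth$psi, sim$truth$gamma, noise_var = 0)
  fit <- structure(
    list(grid = sim$data$grid, index = sim$data$index, J = sim$data$J,
         mu = sim$truth$mu, nu = sim$truth$nu,
         phi = sim$truth$phi, lambda = sim$truth$lambda,
         psi = sim$truth$psi, gamma = sim$truth$gamma,
         scores_subject = sc$scores_subject, scores_meal = sc$scores_meal,
         noise_var = 0),
    class = "mfpca_fit")
  expect_lt(max(abs(reconstruct(fit, "full") - sim$data$Y)), 1e-6)
})

test_that("variance shares follow the eigenvalue sums", {
  toy <- structure(list(lambda = 2, gamma = c(1, 1)), class = "mfpca_fit")
  vp <- variance_proportions(toy)
  expect_equal(vp$share, c(0.5, 0.5))
  expect_equal(sum(vp$share), 1)

  toy2 <- structure(list(lambda = c(3, 1), gamma = numeric(0)),
                    class = "mfpca_fit")
  expect_equal(variance_proportions(toy2)$share, c(1, 0))

  toy0 <- structure(list(lambda = 0, gamma = 0), class = "mfpca_fit")
  expect_error(variance_proportions(toy0), "undefined")
})

test_that("residual sum of squares is non-increasing in H at fixed K", {
  sim <- simulate_mfpca_data(tiny_config(n = 40, J = 3, K = 2, H = 2,
                                         seed = 141))
  rss <- sapply(1:3, function(h) {
    f <- quiet_fit_mfpca(sim$data, K = 2, H = h)
    sum((sim$data$Y - reconstruct(f, "full"))^2)
  })
  expect_true(all(diff(rss) <= 1e-6 * rss[1]))
})
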