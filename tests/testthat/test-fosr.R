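test_that("pointwise fits enforce identifiability and degenerate contracts", {
  g <- make_grid()
  # single subject: random effect inestimable
  d1 <- new_ppg_data(matrix(100, 3, 73), rep("S001", 3), 1:3, g)
  cv1 <- tibble::tibble(subject_id = rep("S001", 3), intercept = 1)
  expect_error(fit_fosr_pointwise(d1, cv1, terms = "intercept"),
               "2 subjects")

  # intercept-only, constant response: exact mean, zero variance components
  d2 <- new_ppg_data(matrix(100, 8, 73), rep(sprintf("S%02d", 1:4), each = 2),
                     rep(1:2, 4), g)
  cv2 <- tibble::tibble(subject_id = d2$index$subject_id, intercept = 1)
  raw <- fit_fosr_pointwise(d2, cv2, terms = "intercept")
  expect_equal(as.vector(raw$beta_raw), rep(100, 73), tolerance = 1e-8)
  expect_lt(max(raw$tau2), 1e-8)
  expect_lt(max(raw$sigma2_eps), 1e-8)

  # rank-deficient design rejected
  cv3 <- tibble::tibble(subject_id = d2$index$subject_id, intercept = 1,
                        dup = 1)
  expect_error(fit_fosr_pointwise(d2, cv3, terms = c("intercept", "dup")),
               "rank deficient")
})

test_that("variance-component collapse reduces to ordinary least squares", {
  sim <- simulate_fosr_data(tiny_config(n = 40, seed = 151,
                                        random_effect_sd = 0))
  raw <- fit_fosr_pointwise(sim$data, sim$covariates)
  collapsed <- which(raw$tau2 < 1e-10)
  expect_gt(length(collapsed), 0)
  for (tt in collapsed[c(1, length(collapsed))]) {
    ols <- qr.coef(qr(raw$X), sim$data$Y[, tt])
    expect_equal(unname(raw$beta_raw[, tt]), unname(ols), tolerance = 1e-6)
  }
})

test_that("coefficient smoothing preserves lines, shrinks noise, can be off", {
  g <- make_grid()
  t <- g$points
  line <- 2 + 0.01 * t
  set.seed(5)
  noise <- stats::rnorm(73, sd = 1)
  raw <- structure(
    list(grid = g, terms = c("a", "b"),
         beta_raw = rbind(a = line, b = noise),
         se_raw = matrix(1, 2, 73, dimnames = list(c("a", "b"), NULL))),
    class = "fosr_pointwise")
  sm <- smooth_coefficients(raw)
  expect_lt(max(abs(sm$beta["a", ] - line)), 1e-6)
  expect_lt(diff(range(sm$beta["b", ])), diff(range(noise)))
  off <- smooth_coefficients(raw, smooth = FALSE)
  expect_identical(off$beta, raw$beta_raw)
})

test_that("random-effect functions are centered and vanish in the null case", {
  sim <- simulate_fosr_data(tiny_config(n = 40, seed = 161,
                                        random_effect_sd = 0))
  raw <- fit_fosr_pointwise(sim$data, sim$covariates)
  alpha <- estimate_random_effect_functions(raw)
  expect_lt(max(abs(colMeans(alpha))), 1e-6)
  expect_lt(max(abs(alpha)), 2.5) # null case at 2 mg/dL noise

  # informative case: recovered functions track the generative truth
  sim2 <- simulate_fosr_data(tiny_config(n = 100, J = 4, seed = 162,
                                         random_effect_sd = 10))
  fit2 <- fit_fosr(sim2$data, sim2$covariates, bands = FALSE)
  al <- fit2$alpha[rownames(sim2$truth$alpha), ]
  cors <- sapply(seq_len(nrow(al)), function(i) {
    stats::cor(al[i, ], sim2$truth$alpha[i, ])
  })
  expect_gt(mean(cors), 0.7)
})

test_that("joint bands dominate pointwise bands and are reproducible", {
  sim <- simulate_fosr_data(tiny_config(n = 30, seed = 171))
  fit <- fit_fosr(sim$data, sim$covariates, B = 200, seed = 5)
  mult <- attr(fit$bands, "multipliers")
  expect_true(all(mult >= stats::qnorm(0.975)))
  expect_true(all(fit$bands$joint_lo <= fit$bands$ptwise_lo + 1e-12))
  expect_true(all(fit$bands$joint_hi >= fit$bands$ptwise_hi - 1e-12))

  fit2 <- fit_fosr(sim$data, sim$covariates, B = 200, seed = 5)
  expect_identical(fit$bands, fit2$bands)

  expect_warning(joint_confidence_bands(fit, B = 50, seed = 1), "unstable")
})

test_that("joint bands for a null effect cover zero in most replicates", {
  hits <- logical(15)
  for (r in seq_along(hits)) {
    cfg <- tiny_config(n = 60, seed = 800 + r,
                       beta_functions = list(
                         intercept = default_mean_function,
                         fats = function(t) 0 * t))
    sim <- simulate_fosr_data(cfg)
    fit <- fit_fosr(sim$data, sim$covariates, B = 300, seed = 800 + r)
    b <- fit$bands[fit$bands$term == "fats", ]
    hits[r] <- all(b$joint_lo <= 0 & b$joint_hi >= 0)
  }
  expect_gte(mean(hits), 0.8)
})

test_that("predictions separate fixed and subject-specific parts exactly", {
  sim <- simulate_fosr_data(tiny_config(n = 30, seed = 181))
  fit <- fit_fosr(sim$data, sim$covariates, bands = FALSE)
  marg <- predict(fit, mode = "marginal")
  cond <- predict(fit, mode = "conditional")
  imap <- match(sim$covariates$subject_id, rownames(fit$alpha))
  expect_equal(cond - marg, fit$alpha[imap, ], tolerance = 1e-12)

  # intercept-only covariate row: marginal prediction is beta_0(t)
  cv0 <- sim$covariates[1, ]
  cv0[setdiff(fit$terms, "intercept")] <- 0
  expect_equal(as.vector(predict(fit, cv0, mode = "marginal")),
               unname(fit$beta["intercept", ]), tolerance = 1e-12)

  # linearity in the design
  c1 <- sim$covariates[3, ]; c2 <- sim$covariates[8, ]
  csum <- c1
  csum[fit$terms] <- c1[fit$terms] + c2[fit$terms]
  expect_equal(predict(fit, csum, mode = "marginal"),
               predict(fit, c1, mode = "marginal") +
                 predict(fit, c2, mode = "marginal"),
               tolerance = 1e-10)

  # marginal predictions ignore subject labels
  relab <- sim$covariates
  relab$subject_id <- rev(relab$subject_id)
  expect_equal(predict(fit, relab, mode = "marginal"),
               predict(fit, sim$covariates, mode = "marginal"))

  unseen <- sim$covariates[1, ]
  unseen$subject_id <- "ZZZ"
  expect_error(predict(fit, unseen, mode = "conditional"), "unseen")
})

test_that("stratified fits recover group-specific coefficient functions", {
  t <- make_grid()$points
  beta_carb_a <- function(t) 0.35 * (t / 60) * exp(1 - t / 60)
  beta_carb_b <- function(t) 0.7 * (t / 60) * exp(1 - t / 60)
  make_group <- function(betafun, seed, label) {
    cfg <- tiny_config(n = 50, seed = seed,
                       beta_functions = list(intercept = default_mean_function,
                                             carbohydrates = betafun))
    sim <- simulate_fosr_data(cfg)
    sim$covariates$group <- label
    sim$covariates$subject_id <- paste0(label, sim$covariates$subject_id)
    sim$data$index$subject_id <- paste0(label, sim$data$index$subject_id)
    sim
  }
  ga <- make_group(beta_carb_a, 191, "normo")
  gb <- make_group(beta_carb_b, 192, "pre")
  data <- ppg_data(rbind(ga$data$Y, gb$data$Y),
                   c(ga$data$index$subject_id, gb$data$index$subject_id),
                   c(ga$data$index$meal, gb$data$index$meal))
  cov <- dplyr::bind_rows(ga$covariates, gb$covariates)
  w <- trapezoid_weights(data$grid)
  fa <- fit_fosr(data, cov, stratum = "normo", bands = FALSE)
  fb <- fit_fosr(data, cov, stratum = "pre", bands = FALSE)
  expect_lt(sum(w * (fa$beta["carbohydrates", ] - beta_carb_a(t))^2), 0.005)
  expect_lt(sum(w * (fb$beta["carbohydrates", ] - beta_carb_b(t))^2), 0.005)
  expect_gt(sum(w * (fb$beta["carbohydrates", ] - beta_carb_a(t))^2), 0.05)

  expect_error(fit_fosr(data, cov, stratum = "nope"), "no rows|selects")
  small <- which(cov$subject_id %in% unique(cov$subject_id)[1:5])
  expect_warning(
    fit_fosr(ppg_subset(data, small), cov[small, ], bands = FALSE),
    "Fewer than 10")
})
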