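# Shared fixtures: small generative configs and independent oracles.

quiet_fit_mfpca <- function(...) suppressWarnings(fit_mfpca(...))

# Small two-level config for fast tests; rank per level and noise settable.
tiny_config <- function(n = 30, J = 3, K = 2, H = 2, noise_sd = 2,
                        seed = 1, subject_share = 0.33, total_var = 144000,
                        ...) {
  g <- make_grid()
  phi <- default_eigenfunctions(g, 3)
  props <- list(`1` = 1, `2` = c(0.7, 0.3), `3` = c(0.6, 0.3, 0.1))
  # meal level uses the trailing library shapes so the two bases are not
  # identical (keeps noiseless interpolation tests non-singular)
  generative_config(
    n_subjects = n, meals_per_subject = J,
    subject_eigenfunctions = phi[, seq_len(K), drop = FALSE],
    subject_eigenvalues = subject_share * total_var * props[[K]],
    meal_eigenfunctions = phi[, 3 + 1 - seq_len(H), drop = FALSE],
    meal_eigenvalues = (1 - subject_share) * total_var * props[[H]],
    noise_sd = noise_sd, seed = seed, ...
  )
}

# Independent brute-force pointwise R2: explicit double loop over curves,
# scalar accumulation only.
brute_force_r2 <- function(observed, fitted) {
  m <- ncol(observed)
  out <- numeric(m)
  for (tt in seq_len(m)) {
    ybar <- 0
    for (i in seq_len(nrow(observed))) ybar <- ybar + observed[i, tt]
    ybar <- ybar / nrow(observed)
    sse <- 0; sst <- 0
    for (i in seq_len(nrow(observed))) {
      sse <- sse + (observed[i, tt] - fitted[i, tt])^2
      sst <- sst + (observed[i, tt] - ybar)^2
    }
    out[tt] <- 1 - sse / sst
  }
  out
}

# Quadrature alignment |<f, g>| of two curves on a grid.
alignment <- function(f, g, grid) {
  abs(quad_inner(f, g, grid))
}
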