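#' Simulate a two-level postprandial curve dataset
#'
#' Draws curves from the hierarchical model
#' `Y_ij(t) = mu(t) + nu_j(t) + sum_k a_ik phi_k(t) + sum_h b_ijh psi_h(t) + e_ij(t)`
#' with independent Gaussian scores (`a_ik ~ N(0, lambda_k)`,
#' `b_ijh ~ N(0, gamma_h)`) and white measurement noise. Subject-level and
#' meal-level draws use separate deterministic substreams of the root seed,
#' so changing the number of meals leaves subject-level draws untouched.
#'
#' @param config A [generative_config()].
#' @return List with `data` (a [ppg_data()]) and `truth`, a list of the
#'   realized generative components (`mu`, `nu`, `phi`, `lambda`,
#'   `scores_subject`, `psi`, `gamma`, `scores_meal` and `noise_sd`)
#'   evaluated on the grid.
#' @export
simulate_mfpca_data <- function(config = generative_config()) {
  validate_config(config)
  grid <- config$grid
  t <- grid$points
  m <- length(t)
  n <- config$n_subjects
  J <- meal_counts(config)
  K <- length(config$subject_eigenvalues)
  H <- length(config$meal_eigenvalues)
  phi <- config$subject_eigenfunctions
  psi <- config$meal_eigenfunctions
  mu <- config$mean_function(t)
  maxJ <- max(J)
  nu <- if (is.null(config$day_effects)) {
    matrix(0, maxJ, m)
  } else {
    as.matrix(config$day_effects)
  }
  if (nrow(nu) < maxJ) stop("`day_effects` has fewer rows than max J_i.",
                            call. = FALSE)

  ids <- sprintf("S%03d", seq_len(n))

  set.seed(substream_seed(config$seed, 1L))
  a <- matrix(stats::rnorm(n * K), n, K) %*%
    diag(sqrt(config$subject_eigenvalues), K)

  rows <- sum(J)
  Y <- matrix(0, rows, m)
  subj <- character(rows)
  meal <- integer(rows)
  b <- matrix(0, rows, H)
  r <- 0L
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, 1000L + i))
    bi <- matrix(stats::rnorm(J[i] * H), J[i], H) %*%
      diag(sqrt(config$meal_eigenvalues), H)
    eps <- matrix(stats::rnorm(J[i] * m, sd = config$noise_sd), J[i], m)
    Ui <- as.vector(phi %*% a[i, ])
    for (j in seq_len(J[i])) {
      r <- r + 1L
      Y[r, ] <- mu + nu[j, ] + Ui + as.vector(psi %*% bi[j, ]) + eps[j, ]
      subj[r] <- ids[i]
      meal[r] <- j
      b[r, ] <- bi[j, ]
    }
  }

  data <- new_ppg_data(Y, subj, meal, grid)
  truth <- structure(
    list(
      grid = grid, mu = mu, nu = nu,
      phi = phi, lambda = config$subject_eigenvalues,
      scores_subject = structure(a, dimnames = list(ids, NULL)),
      psi = psi, gamma = config$meal_eigenvalues,
      scores_meal = tibble::tibble(subject_id = subj, meal = meal) |>
        dplyr::bind_cols(tibble::as_tibble(b, .name_repair = ~ paste0("b", seq_len(H)))),
      noise_sd = config$noise_sd
    ),
    class = "cgm_truth"
  )
  list(data = data, truth = truth)
}

#' Simulate a function-on-scalar regression dataset
#'
#' Draws curves from
#' `Y_ij(t) = sum_l X_ij,l beta_l(t) + alpha_i(t) + e_ij(t)`, with
#' subject-level covariates held constant across a subject's meals,
#' `alpha_i(t)` a zero-mean squared-exponential Gaussian process (marginal sd
#' `random_effect_sd`, length-scale `random_effect_lengthscale`), and white
#' measurement noise.
#'
#' @param config A [generative_config()]. `beta_functions` names must be
#'   `"intercept"` or names present in `covariate_spec`.
#' @return List with `data` (a [ppg_data()]), `covariates` (tibble, one row
#'   per curve: `subject_id`, `meal`, `intercept`, covariate columns) and
#'   `truth` (list with `beta` matrix `L x m`, `alpha` matrix `n x m`,
#'   covariate names, `noise_sd`).
#' @export
simulate_fosr_data <- function(config = generative_config()) {
  grid <- config$grid
  t <- grid$points
  m <- length(t)
  n <- config$n_subjects
  J <- meal_counts(config)
  ids <- sprintf("S%03d", seq_len(n))

  bnames <- names(config$beta_functions)
  cnames <- setdiff(bnames, "intercept")
  unknown <- setdiff(cnames, names(config$covariate_spec))
  if (length(unknown)) {
    stop("beta_functions name(s) without covariate_spec entry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  # subject-level draws: covariates and random-effect functions
  set.seed(substream_seed(config$seed, 2L))
  subj_cov <- list()
  for (nm in cnames) {
    sp <- config$covariate_spec[[nm]]
    if (sp$level == "subject") subj_cov[[nm]] <- sp$draw(n)
  }
  alpha <- matrix(0, n, m)
  if (config$random_effect_sd > 0) {
    D <- outer(t, t, function(a, b) {
      exp(-0.5 * ((a - b) / config$random_effect_lengthscale)^2)
    })
    L <- chol(config$random_effect_sd^2 * D + diag(1e-8, m))
    alpha <- matrix(stats::rnorm(n * m), n, m) %*% L
    alpha <- sweep(alpha, 2, colMeans(alpha)) # identifiability: mean zero
  }

  rows <- sum(J)
  X <- matrix(0, rows, length(bnames),
              dimnames = list(NULL, bnames))
  subj <- character(rows)
  meal <- integer(rows)
  r <- 0L
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, 5000L + i))
    meal_cov <- list()
    for (nm in cnames) {
      sp <- config$covariate_spec[[nm]]
      meal_cov[[nm]] <- if (sp$level == "meal") sp$draw(J[i]) else
        rep(subj_cov[[nm]][i], J[i])
    }
    for (j in seq_len(J[i])) {
      r <- r + 1L
      subj[r] <- ids[i]
      meal[r] <- j
      if ("intercept" %in% bnames) X[r, "intercept"] <- 1
      for (nm in cnames) X[r, nm] <- meal_cov[[nm]][j]
    }
  }

  const_cols <- cnames[vapply(cnames, function(nm) {
    stats::var(X[, nm]) < .Machine$double.eps
  }, logical(1))]
  if ("intercept" %in% bnames && length(const_cols)) {
    warning("Constant covariate column(s) alongside an intercept ",
            "(collinear design): ", paste(const_cols, collapse = ", "))
  }

  B <- vapply(bnames, function(nm) config$beta_functions[[nm]](t), numeric(m))
  Y <- X %*% t(B)
  imap <- match(subj, ids)
  Y <- Y + alpha[imap, , drop = FALSE]
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, 9000L + i))
    sel <- which(imap == i)
    Y[sel, ] <- Y[sel, ] +
      matrix(stats::rnorm(length(sel) * m, sd = config$noise_sd),
             length(sel), m)
  }

  covariates <- tibble::tibble(subject_id = subj, meal = meal) |>
    dplyr::bind_cols(tibble::as_tibble(X))
  data <- new_ppg_data(Y, subj, meal, grid)
  truth <- structure(
    list(
      grid = grid,
      beta = t(B), # L x m
      beta_names = bnames,
      alpha = structure(alpha, dimnames = list(ids, NULL)),
      noise_sd = config$noise_sd
    ),
    class = "cgm_truth"
  )
  list(data = data, covariates = covariates, truth = truth)
}

#' Simulate a raw multi-day CGM stream with meal log
#'
#' Fixture generator for the preprocessing filters: a multi-day 5-minute
#' stream per subject with one dinner per day at a configurable clock time.
#' Postprandial segments follow the two-level model of
#' [simulate_mfpca_data()] superimposed on a basal level; scripted missing
#' runs are injected per `gap_spec` (signal loss, i.e. the timestamps are
#' absent).
#'
#' @param config A [generative_config()].
#' @param days Days of wear.
#' @param gap_spec List of gaps, each `list(day =, start_minute =,
#'   duration =, subject_id = )` (`subject_id` optional: default all
#'   subjects). `start_minute` is minutes after that day's midnight.
#'   Overlapping gaps are merged with a warning.
#' @param dinner_minute Dinner clock time, minutes after midnight (default
#'   1230 = 20:30).
#' @param start_date First day of wear (Date).
#' @return List with `stream` (tibble `subject_id`, `time` (POSIXct UTC),
#'   `glucose`) and `meals` (tibble `subject_id`, `meal_time`, `meal_label`,
#'   nutrient grams).
#' @export
simulate_raw_cgm_stream <- function(config = generative_config(),
                                    days = 7,
                                    gap_spec = NULL,
                                    dinner_minute = 1230,
                                    start_date = as.Date("2024-03-01")) {
  validate_config(config)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  per_day <- 288L
  offsets <- seq(0, days * 24 * 60 - 5, by = 5) # minutes since t0
  grid_t <- config$grid$points
  phi <- config$subject_eigenfunctions
  psi <- config$meal_eigenfunctions
  mu <- config$mean_function(grid_t)
  basal <- 95

  set.seed(substream_seed(config$seed, 3L))
  a <- matrix(stats::rnorm(n * ncol(phi)), n, ncol(phi)) %*%
    diag(sqrt(config$subject_eigenvalues), ncol(phi))

  # resolve gaps to per-subject sets of dropped offsets
  gap_minutes <- function(g) {
    if (g$day < 1 || g$day > days) {
      stop("gap day ", g$day, " outside the simulated span.", call. = FALSE)
    }
    from <- (g$day - 1) * 1440 + g$start_minute
    if (from + g$duration > days * 1440) {
      stop("gap extends past the simulated span.", call. = FALSE)
    }
    seq(from, from + g$duration - 5, by = 5)
  }

  streams <- vector("list", n)
  meal_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, 20000L + i))
    glucose <- basal + stats::rnorm(length(offsets), sd = max(config$noise_sd, 0.5))
    Ui <- as.vector(phi %*% a[i, ])
    for (d in seq_len(days)) {
      b <- as.vector(psi %*% (stats::rnorm(ncol(psi)) *
                                sqrt(config$meal_eigenvalues)))
      meal_off <- (d - 1) * 1440 + dinner_minute
      resp <- mu - basal + Ui + b
      idx <- match(meal_off + grid_t, offsets)
      ok <- !is.na(idx)
      glucose[idx[ok]] <- basal + resp[ok] +
        stats::rnorm(sum(ok), sd = config$noise_sd)
      meal_rows[[i]][[d]] <- tibble::tibble(
        subject_id = ids[i],
        meal_time = t0 + (meal_off) * 60,
        meal_label = "dinner",
        carbohydrates = round(max(stats::rnorm(1, 59.9, 40.5), 0), 1),
        fats = round(max(stats::rnorm(1, 30.1, 23.8), 0), 1),
        proteins = round(max(stats::rnorm(1, 27.5, 17.9), 0), 1),
        fiber = round(max(stats::rnorm(1, 8.8, 6.7), 0), 1)
      )
    }
    drop <- integer(0)
    if (!is.null(gap_spec)) {
      mins_list <- list()
      for (g in gap_spec) {
        if (!is.null(g$subject_id) && g$subject_id != ids[i]) next
        mins_list[[length(mins_list) + 1]] <- gap_minutes(g)
      }
      if (length(mins_list)) {
        all_mins <- unlist(mins_list)
        if (anyDuplicated(all_mins)) {
          warning("Overlapping gaps merged for subject ", ids[i], ".")
        }
        drop <- match(unique(all_mins), offsets)
        drop <- drop[!is.na(drop)]
      }
    }
    keep <- setdiff(seq_along(offsets), drop)
    streams[[i]] <- tibble::tibble(
      subject_id = ids[i],
      time = t0 + offsets[keep] * 60,
      glucose = round(glucose[keep], 2)
    )
  }

  list(
    stream = dplyr::bind_rows(streams),
    meals = dplyr::bind_rows(lapply(meal_rows, dplyr::bind_rows))
  )
}

#' Simulate a subject-covariate table matching a simulated stream
#'
#' Subject-level fields (age, weight, gender, HbA1c, glycemic group) for the
#' subjects of a [simulate_raw_cgm_stream()] run. Group labels follow an
#' HbA1c cut at 5.7% (normoglycemic below, prediabetes at or above).
#'
#' @param config A [generative_config()].
#' @return Tibble, one row per subject.
#' @export
simulate_subject_table <- function(config = generative_config()) {
  n <- config$n_subjects
  set.seed(substream_seed(config$seed, 4L))
  hba1c <- round(pmin(pmax(stats::rnorm(n, 5.35, 0.3), 4.2), 6.4), 2)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(pmin(pmax(stats::rnorm(n, 46, 14), 18), 85), 1),
    weight = round(pmin(pmax(stats::rnorm(n, 75, 15), 40), 145), 1),
    gender_male = stats::rbinom(n, 1, 0.37),
    hba1c = hba1c,
    group = ifelse(hba1c >= 5.7, "prediabetes", "normoglycemic")
  )
}
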