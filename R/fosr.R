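#' Pointwise mixed-model fit of the function-on-scalar regression
#'
#' At every grid point `t` fits the linear mixed model
#' `Y_ij(t) = x_ij' beta(t) + alpha_i(t) + e_ij(t)` by REML (fixed effects
#' plus a random intercept per subject), via `lme4`. Where the random-effect
#' variance collapses to the boundary the fit degenerates to ordinary least
#' squares; those points are recorded.
#'
#' @param data A [ppg_data()].
#' @param covariates Covariate tibble aligned to `data` rows; must contain
#'   `subject_id` and the design columns.
#' @param terms Character vector of design columns (default: every numeric
#'   column other than `meal`).
#' @return Object of class `fosr_pointwise` with raw coefficient curves
#'   `beta_raw` (`L x m`), standard errors `se_raw`, per-point variance
#'   components `sigma2_eps` and `tau2`, raw subject predictions
#'   `alpha_raw` (`n x m`), the design matrix and bookkeeping.
#' @export
fit_fosr_pointwise <- function(data, covariates, terms = NULL) {
  stopifnot(nrow(covariates) == nrow(data$Y))
  if (!identical(covariates$subject_id, data$index$subject_id)) {
    stop("`covariates` rows must align with `data` rows (subject_id).",
         call. = FALSE)
  }
  if (data$n < 2) {
    stop("Random subject effects need at least 2 subjects.", call. = FALSE)
  }
  if (is.null(terms)) {
    terms <- names(covariates)[vapply(covariates, is.numeric, logical(1))]
    terms <- setdiff(terms, c("meal"))
  }
  X <- as.matrix(covariates[, terms, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    stop("Design matrix is rank deficient for terms: ",
         paste(terms, collapse = ", "), call. = FALSE)
  }
  m <- length(data$grid$points)
  L <- ncol(X)
  subj <- factor(data$index$subject_id)
  n <- nlevels(subj)

  beta_raw <- matrix(NA_real_, L, m, dimnames = list(terms, NULL))
  se_raw <- matrix(NA_real_, L, m, dimnames = list(terms, NULL))
  sigma2 <- numeric(m)
  tau2 <- numeric(m)
  alpha_raw <- matrix(0, n, m, dimnames = list(levels(subj), NULL))
  singular <- logical(m)

  df <- data.frame(y = data$Y[, 1], subj = subj)
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  base_fit <- suppressMessages(
    lme4::lmer(y ~ 0 + X + (1 | subj), data = df, REML = TRUE,
               control = ctrl))
  for (tt in seq_len(m)) {
    fit <- if (tt == 1) base_fit else
      suppressMessages(suppressWarnings(
        lme4::refit(base_fit, newresp = data$Y[, tt])))
    beta_raw[, tt] <- lme4::fixef(fit)
    # vcov can fail on fully degenerate (zero-variance) fits; the fixed
    # effects are then exact and their sampling variance is zero
    V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                  error = function(e) matrix(0, L, L))
    dv <- diag(V)
    dv[!is.finite(dv)] <- 0
    se_raw[, tt] <- sqrt(pmax(dv, 0))
    vc <- lme4::VarCorr(fit)
    tau2[tt] <- as.numeric(vc$subj[1, 1])
    sigma2[tt] <- stats::sigma(fit)^2
    singular[tt] <- lme4::isSingular(fit)
    re <- lme4::ranef(fit)$subj
    alpha_raw[rownames(re), tt] <- re[, 1]
  }
  structure(
    list(
      grid = data$grid, terms = terms, X = X, subject = subj,
      index = data$index, Y = data$Y,
      beta_raw = beta_raw, se_raw = se_raw,
      sigma2_eps = sigma2, tau2 = tau2,
      alpha_raw = alpha_raw, singular = singular
    ),
    class = "fosr_pointwise"
  )
}

#' Smooth raw pointwise coefficient curves
#'
#' Each raw coefficient curve is smoothed across `t` with a penalized
#' spline (REML smoothness selection); the pointwise variance curve is
#' smoothed on the same basis and carried forward as the standard error of
#' the smoothed coefficient. `smooth = FALSE` (the zero-penalty option)
#' returns the raw curves unchanged.
#'
#' @param raw A `fosr_pointwise`.
#' @param smooth Apply smoothing?
#' @return List with `beta` and `beta_se` (both `L x m`).
#' @export
smooth_coefficients <- function(raw, smooth = TRUE) {
  t <- raw$grid$points
  if (!smooth) {
    return(list(beta = raw$beta_raw, beta_se = raw$se_raw))
  }
  L <- nrow(raw$beta_raw)
  beta <- raw$beta_raw
  se <- raw$se_raw
  for (l in seq_len(L)) {
    beta[l, ] <- tryCatch(
      smooth_curve(raw$beta_raw[l, ], t),
      error = function(e) {
        warning("Smoothing failed for term '", rownames(raw$beta_raw)[l],
                "'; fixed moderate penalty used.")
        as.vector(stats::fitted(mgcv::gam(
          raw$beta_raw[l, ] ~ s(t, k = 15, bs = "ps", sp = 1))))
      })
    v <- smooth_curve(raw$se_raw[l, ]^2, t)
    se[l, ] <- sqrt(pmax(v, 1e-12))
  }
  list(beta = beta, beta_se = se)
}

#' Subject random-effect functions from pointwise predictions
#'
#' The per-subject pointwise predicted effects are smoothed across `t` and
#' centered so the across-subject mean is exactly zero at every grid point.
#'
#' @param raw A `fosr_pointwise`.
#' @param smooth Smooth across `t`?
#' @return Matrix `n x m` of `alpha_i(t)`, rownames = subject ids.
#' @export
estimate_random_effect_functions <- function(raw, smooth = TRUE) {
  alpha <- raw$alpha_raw
  if (smooth && nrow(alpha)) {
    t <- raw$grid$points
    for (i in seq_len(nrow(alpha))) {
      if (stats::sd(alpha[i, ]) > 1e-12) {
        alpha[i, ] <- stats::smooth.spline(t, alpha[i, ])$y
      }
    }
  }
  sweep(alpha, 2, colMeans(alpha))
}

#' Joint and pointwise confidence bands for coefficient functions
#'
#' Pointwise bands are `beta_hat +/- z * se`. Joint (simultaneous) bands
#' rescale the same standard-error curve by a multiplier estimated from a
#' subject-level (cluster) bootstrap of the maximum standardized deviation
#' over the grid: subjects are resampled with replacement and the
#' coefficients re-estimated by pointwise generalized least squares with the
#' variance components frozen at their REML estimates. The multiplier is
#' floored at `z`, so the joint band always contains the pointwise band.
#'
#' @param fit A `fosr_fit` (from [fit_fosr()]).
#' @param level Coverage level (default 0.95).
#' @param B Bootstrap resamples (default 1000; below 100 raises a warning).
#' @param seed Integer seed making the bands reproducible.
#' @return Tibble with one row per (term, t): `term`, `t`, `estimate`,
#'   `se`, `ptwise_lo`, `ptwise_hi`, `joint_lo`, `joint_hi`; multipliers in
#'   attribute `"multipliers"`.
#' @export
joint_confidence_bands <- function(fit, level = 0.95, B = 1000, seed = 1) {
  if (B < 100) warning("B < 100 gives an unstable joint-band quantile.")
  z <- stats::qnorm((1 + level) / 2)
  t <- fit$grid$points
  m <- length(t)
  L <- length(fit$terms)
  X <- fit$X
  subj <- fit$subject
  n <- nlevels(subj)
  sigma2 <- pmax(fit$sigma2_eps, 1e-8)
  tau2 <- pmax(fit$tau2, 0)

  # Per-subject sufficient statistics for frozen-variance GLS:
  # A_i(t) = (X_i'X_i - w_it s_i s_i') / sigma2_t, w_it = tau2/(sigma2+J_i tau2)
  rows <- split(seq_len(nrow(X)), subj)
  Ji <- lengths(rows)
  P <- array(0, c(L, L, n))
  S <- array(0, c(L, L, n))
  U <- array(0, c(L, m, n))  # X_i' Y_i
  Smat <- matrix(0, L, n)    # column sums s_i of X_i
  cy <- matrix(0, n, m)      # column sums of Y_i
  for (i in seq_len(n)) {
    Xi <- X[rows[[i]], , drop = FALSE]
    Yi <- fit$Y[rows[[i]], , drop = FALSE]
    si <- colSums(Xi)
    P[, , i] <- crossprod(Xi)
    S[, , i] <- outer(si, si)
    U[, , i] <- crossprod(Xi, Yi)
    Smat[, i] <- si
    cy[i, ] <- colSums(Yi)
  }
  Pm <- matrix(P, L * L, n); Sm <- matrix(S, L * L, n)
  Um <- matrix(U, L * m, n)
  # n x m matrix of shrinkage weights w_it
  Wt <- sapply(seq_len(m), function(tt) tau2[tt] / (sigma2[tt] + Ji * tau2[tt]))
  if (n == 1) Wt <- matrix(Wt, nrow = 1)

  gls_beta <- function(counts) {
    cP <- matrix(Pm %*% counts, L, L)
    bU <- matrix(Um %*% counts, L, m)
    cS <- Sm %*% (counts * Wt)            # L^2 x m
    bV <- Smat %*% (counts * Wt * cy)     # L x m
    beta <- matrix(0, L, m)
    for (tt in seq_len(m)) {
      A <- cP - matrix(cS[, tt], L, L)
      b <- bU[, tt] - bV[, tt]
      beta[, tt] <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, L))
    }
    beta
  }

  beta_hat <- gls_beta(rep(1, n))
  se <- fit$beta_se
  set.seed(substream_seed(seed, 77L))
  dev_max <- matrix(0, B, L)
  for (b in seq_len(B)) {
    counts <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    bb <- gls_beta(counts)
    dev_max[b, ] <- apply(abs(bb - beta_hat) / se, 1, max, na.rm = TRUE)
  }
  mult <- pmax(apply(dev_max, 2, stats::quantile, probs = level,
                     na.rm = TRUE, names = FALSE), z)

  out <- tibble::tibble(
    term = rep(fit$terms, each = m),
    t = rep(t, L),
    estimate = as.vector(t(fit$beta)),
    se = as.vector(t(se)),
    ptwise_lo = as.vector(t(fit$beta - z * se)),
    ptwise_hi = as.vector(t(fit$beta + z * se)),
    joint_lo = as.vector(t(fit$beta - mult * se)),
    joint_hi = as.vector(t(fit$beta + mult * se))
  )
  attr(out, "multipliers") <- stats::setNames(mult, fit$terms)
  out
}

#' Fit a function-on-scalar regression with subject random-effect functions
#'
#' Two-step estimation: pointwise linear mixed models at every grid point
#' ([fit_fosr_pointwise()]), penalized-spline smoothing of the coefficient
#' curves ([smooth_coefficients()]), smoothed and centered subject
#' random-effect functions, and (optionally) pointwise plus joint
#' confidence bands. With `stratum` set, the model is fitted on the subset
#' of rows whose `group` column matches (stratified, not pooled).
#'
#' @inheritParams fit_fosr_pointwise
#' @param stratum Optional `group` label to subset on.
#' @param smooth Smooth coefficient and random-effect curves?
#' @param bands Compute confidence bands?
#' @param level,B,seed Band options, see [joint_confidence_bands()].
#' @return Object of class `fosr_fit`.
#' @export
fit_fosr <- function(data, covariates, terms = NULL, stratum = NULL,
                     smooth = TRUE, bands = TRUE, level = 0.95, B = 1000,
                     seed = 1) {
  if (!is.null(stratum)) {
    if (!"group" %in% names(covariates)) {
      stop("`stratum` given but `covariates` has no `group` column.",
           call. = FALSE)
    }
    keep <- which(covariates$group == stratum)
    if (!length(keep)) stop("Stratum '", stratum, "' selects no rows.",
                            call. = FALSE)
    data <- ppg_subset(data, keep)
    covariates <- covariates[keep, , drop = FALSE]
  }
  if (data$n < 10) {
    warning("Fewer than 10 subjects in this fit; confidence bands may be ",
            "unreliable.")
  }
  raw <- fit_fosr_pointwise(data, covariates, terms)
  sm <- smooth_coefficients(raw, smooth = smooth)
  alpha <- estimate_random_effect_functions(raw, smooth = smooth)
  fit <- structure(
    list(
      grid = raw$grid, terms = raw$terms,
      beta = sm$beta, beta_se = sm$beta_se,
      beta_raw = raw$beta_raw, se_raw = raw$se_raw,
      alpha = alpha,
      sigma2_eps = raw$sigma2_eps, tau2 = raw$tau2,
      singular = raw$singular,
      X = raw$X, Y = raw$Y, subject = raw$subject, index = raw$index,
      stratum = stratum %||% "all",
      level = level, B = B, seed = seed,
      bands = NULL
    ),
    class = "fosr_fit"
  )
  if (bands) {
    fit$bands <- joint_confidence_bands(fit, level = level, B = B,
                                        seed = seed)
  }
  fit
}

#' @export
print.fosr_fit <- function(x, ...) {
  cat("<fosr_fit> stratum '", x$stratum, "': ", length(x$terms),
      " coefficient functions, ", nlevels(x$subject), " subjects, ",
      nrow(x$Y), " curves\n", sep = "")
  invisible(x)
}

#' Predict curves from a fitted function-on-scalar regression
#'
#' `"marginal"` predictions use the fixed part `X beta(t)` only;
#' `"conditional"` predictions add the subject random-effect function
#' `alpha_i(t)` (known subjects only), so conditional minus marginal equals
#' `alpha_i(t)` exactly.
#'
#' @param object A `fosr_fit`.
#' @param covariates Covariate tibble with the model's design columns (and
#'   `subject_id` for conditional predictions). Defaults to the training
#'   design.
#' @param mode `"marginal"` or `"conditional"`.
#' @param ... Unused.
#' @return Matrix of predicted curves, one row per covariate row.
#' @export
predict.fosr_fit <- function(object, covariates = NULL,
                             mode = c("marginal", "conditional"), ...) {
  mode <- match.arg(mode)
  if (is.null(covariates)) {
    X <- object$X
    subj <- as.character(object$subject)
  } else {
    X <- as.matrix(covariates[, object$terms, drop = FALSE])
    subj <- covariates$subject_id
  }
  pred <- X %*% object$beta
  if (mode == "conditional") {
    if (is.null(subj)) {
      stop("Conditional predictions need `subject_id`.", call. = FALSE)
    }
    imap <- match(subj, rownames(object$alpha))
    if (anyNA(imap)) {
      stop("Conditional prediction requested for unseen subject(s): ",
           paste(unique(subj[is.na(imap)]), collapse = ", "),
           "; use mode = \"marginal\".", call. = FALSE)
    }
    pred <- pred + object$alpha[imap, , drop = FALSE]
  }
  pred
}

# Row subset of a ppg_data, keeping grid and re-deriving counts.
ppg_subset <- function(data, rows) {
  new_ppg_data(data$Y[rows, , drop = FALSE],
               data$index$subject_id[rows],
               data$index$meal[rows],
               data$grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
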