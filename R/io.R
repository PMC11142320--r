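# Readers and writers for the package's persisted artifact types. All
# numeric text output is formatted at 12 significant digits so re-runs are
# byte-comparable.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.12g", v)
  }, character(1))
  out
}

write_plain_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- fmt_num(df[[nm]])
    if (inherits(df[[nm]], "POSIXct")) {
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a postprandial curve dataset as long CSV
#'
#' Schema: `subject_id, meal_index, t_minutes, glucose_mgdl`. Reading
#' canonicalizes row order (subject, meal, t), so a row-shuffled file
#' reads back to the identical dataset.
#'
#' @param data A [ppg_data()].
#' @param path CSV path.
#' @return `write_ppg_csv`: the path, invisibly. `read_ppg_csv`: a
#'   [ppg_data()].
#' @export
write_ppg_csv <- function(data, path) {
  long <- tidy.ppg_data(data)
  names(long) <- c("subject_id", "meal_index", "t_minutes", "glucose_mgdl")
  write_plain_csv(long, path)
}

#' @rdname write_ppg_csv
#' @export
read_ppg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "meal_index", "t_minutes", "glucose_mgdl")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Missing required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), need)
  if (length(extra)) warning("Ignoring unknown column(s): ",
                             paste(extra, collapse = ", "))
  ppg_data(tibble::tibble(subject_id = df$subject_id,
                          meal = df$meal_index,
                          t = df$t_minutes,
                          glucose = df$glucose_mgdl))
}

#' Write / read a raw CGM stream as long CSV
#'
#' Schema: `subject_id, timestamp` (ISO-8601 UTC), `glucose_mgdl`. Reading
#' enforces strictly increasing timestamps within subject.
#'
#' @param stream Stream tibble (`subject_id`, `time`, `glucose`).
#' @param path CSV path.
#' @return `write_cgm_csv`: path, invisibly. `read_cgm_csv`: stream tibble.
#' @export
write_cgm_csv <- function(stream, path) {
  write_plain_csv(
    tibble::tibble(subject_id = stream$subject_id,
                   timestamp = stream$time,
                   glucose_mgdl = stream$glucose),
    path)
}

#' @rdname write_cgm_csv
#' @export
read_cgm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "glucose_mgdl")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Missing required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), need)
  if (length(extra)) warning("Ignoring unknown column(s): ",
                             paste(extra, collapse = ", "))
  out <- tibble::tibble(
    subject_id = df$subject_id,
    time = as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                      tz = "UTC"),
    glucose = df$glucose_mgdl
  )
  validate_stream(out)
  out
}

#' Write / read a covariate table CSV (one row per curve)
#'
#' @param covariates Covariate tibble.
#' @param path CSV path.
#' @return `write_covariates_csv`: path, invisibly. `read_covariates_csv`:
#'   tibble.
#' @export
write_covariates_csv <- function(covariates, path) {
  write_plain_csv(covariates, path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize generative ground truth to a JSON sidecar
#'
#' @param truth A `cgm_truth` from a simulator.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- lapply(unclass(truth), function(x) {
    if (inherits(x, "cgm_grid")) list(points = x$points, step = x$step)
    else if (is.matrix(x)) unname(apply(x, 1, identity, simplify = FALSE))
    else if (is.data.frame(x)) x
    else x
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       dataframe = "columns")
  invisible(path)
}

#' Write a model summary JSON
#'
#' For an `mfpca_fit`: eigenvalues, variance shares, noise variance. For a
#' `fosr_fit`: terms, variance-component summaries, band multipliers.
#'
#' @param model An `mfpca_fit` or `fosr_fit`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- if (inherits(model, "mfpca_fit")) {
    vp <- variance_proportions(model)
    list(model = "mfpca", K = ncol(model$phi), H = ncol(model$psi),
         lambda = model$lambda, gamma = model$gamma,
         subject_share = vp$share[vp$level == "subject"],
         meal_share = vp$share[vp$level == "meal"],
         noise_var = model$noise_var)
  } else if (inherits(model, "fosr_fit")) {
    list(model = "fosr", stratum = model$stratum, terms = model$terms,
         n_subjects = nlevels(model$subject), n_curves = nrow(model$Y),
         level = model$level, B = model$B, seed = model$seed,
         multipliers = if (!is.null(model$bands))
           as.list(attr(model$bands, "multipliers")) else NULL,
         mean_sigma2_eps = mean(model$sigma2_eps),
         mean_tau2 = mean(model$tau2))
  } else {
    stop("Unsupported model class.", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
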