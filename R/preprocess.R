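#' Apply CGM quality filters
#'
#' Conservative day-level quality control of a raw CGM stream, per subject:
#' the entire first calendar day of wear (midnight-to-midnight) is discarded,
#' and any later 24-h day containing a missing run strictly longer than
#' `max_gap_minutes` (default 120 min) is removed entirely. Missing runs are
#' stretches with no usable observation, whether from absent timestamps or
#' `NA` glucose; runs are clipped to day boundaries. An optional per-day
#' predicate hook (e.g. a calibration-count check, when such a channel
#' exists) can exclude further days.
#'
#' Filtering is idempotent: the returned stream carries a `cgm_filtered`
#' attribute and a second application returns it unchanged.
#'
#' @param stream Tibble with columns `subject_id`, `time` (POSIXct),
#'   `glucose`; timestamps strictly increasing within subject.
#' @param max_gap_minutes Longest tolerated missing run within a day;
#'   strictly longer runs exclude the day.
#' @param drop_first_day Drop the first calendar day of wear per subject.
#' @param day_predicate Optional `function(day_data) -> logical(1)`; days for
#'   which it returns `FALSE` are excluded with reason
#'   `"predicate"`.
#' @return List with `stream` (the filtered tibble) and `exclusions`
#'   (tibble: `subject_id`, `day`, `reason`).
#' @export
apply_quality_filters <- function(stream,
                                  max_gap_minutes = 120,
                                  drop_first_day = TRUE,
                                  day_predicate = NULL) {
  validate_stream(stream)
  if (isTRUE(attr(stream, "cgm_filtered"))) {
    return(list(stream = stream,
                exclusions = tibble::tibble(subject_id = character(),
                                            day = as.Date(character()),
                                            reason = character())))
  }
  excl <- list()
  keep <- logical(nrow(stream))
  day <- as.Date(stream$time, tz = "UTC")
  for (sid in unique(stream$subject_id)) {
    sel <- which(stream$subject_id == sid)
    sdays <- day[sel]
    udays <- sort(unique(sdays))
    span_h <- as.numeric(difftime(max(stream$time[sel]),
                                  min(stream$time[sel]), units = "hours"))
    if (span_h < 24) {
      warning("Subject ", sid, ": stream shorter than 24 h; ",
              "all data excluded.")
    }
    for (d in seq_along(udays)) {
      dsel <- sel[sdays == udays[d]]
      if (drop_first_day && d == 1) {
        excl[[length(excl) + 1]] <- tibble::tibble(
          subject_id = sid, day = udays[d], reason = "first_day")
        next
      }
      gap <- max_missing_run_minutes(stream$time[dsel], stream$glucose[dsel],
                                     day_start = as.POSIXct(paste(udays[d], "00:00:00"),
                                                            tz = "UTC"))
      if (gap > max_gap_minutes) {
        excl[[length(excl) + 1]] <- tibble::tibble(
          subject_id = sid, day = udays[d],
          reason = sprintf("gap_%g_min", gap))
        next
      }
      if (!is.null(day_predicate) && !isTRUE(day_predicate(stream[dsel, ]))) {
        excl[[length(excl) + 1]] <- tibble::tibble(
          subject_id = sid, day = udays[d], reason = "predicate")
        next
      }
      keep[dsel] <- TRUE
    }
  }
  out <- stream[keep, , drop = FALSE]
  attr(out, "cgm_filtered") <- TRUE
  list(
    stream = out,
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(subject_id = character(), day = as.Date(character()),
                     reason = character())
  )
}

# Longest missing run (minutes) within one day's records at the nominal
# 5-min cadence. A run between consecutive usable samples Delta minutes
# apart has length Delta - 5; runs are clipped to the day's
# midnight-to-midnight span (nominal samples at 0, 5, ..., 1435 min).
max_missing_run_minutes <- function(times, glucose, day_start) {
  ok <- !is.na(glucose)
  tt <- sort(as.numeric(times[ok])) / 60 # minutes since epoch
  d0 <- as.numeric(day_start) / 60
  if (!length(tt)) return(1440)
  runs <- c(tt[1] - d0, diff(tt) - 5, (d0 + 1435) - tt[length(tt)])
  max(0, runs)
}

validate_stream <- function(stream) {
  need <- c("subject_id", "time", "glucose")
  miss <- setdiff(need, names(stream))
  if (length(miss)) {
    stop("CGM stream lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- stream |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mono = !is.unsorted(.data$time, strictly = TRUE)) |>
    dplyr::filter(!.data$mono)
  if (nrow(bad)) {
    stop("Timestamps not strictly increasing for subject(s): ",
         paste(bad$subject_id, collapse = ", "), call. = FALSE)
  }
  invisible(stream)
}

#' Extract aligned postprandial windows
#'
#' For each retained meal of the requested label, samples the stream at
#' `meal_time + grid` offsets (nearest observation within half the cadence,
#' ties broken toward the later sample) to build one curve per meal. A
#' window is retained iff at least `min_prop_observed` of grid points are
#' observed and no missing run exceeds `max_internal_gap` minutes; interior
#' gaps up to that length are linearly interpolated and edge runs filled by
#' nearest-value extension. Windows of meals less than the window length
#' apart are retained but flagged as overlapping.
#'
#' @param stream Quality-filtered CGM stream tibble.
#' @param meals Meal-log tibble with `subject_id`, `meal_time`, `meal_label`.
#' @param grid A `cgm_grid` of window offsets (minutes after the meal).
#' @param meal_label Which meals to extract (default `"dinner"`).
#' @param min_prop_observed Minimum observed fraction of grid points.
#' @param max_internal_gap Longest interpolable missing run, minutes.
#' @return A [ppg_data()] whose rows are the surviving windows, ordered by
#'   subject then meal time, with attribute `"window_log"`: a tibble with
#'   one row per candidate meal (`subject_id`, `meal_time`, `n_observed`,
#'   `kept`, `reason`, `overlaps`).
#' @export
extract_windows <- function(stream, meals, grid = make_grid(),
                            meal_label = "dinner",
                            min_prop_observed = 0.8,
                            max_internal_gap = 30) {
  validate_stream(stream)
  meals <- meals[meals$meal_label == meal_label, , drop = FALSE]
  meals <- dplyr::arrange(meals, .data$subject_id, .data$meal_time)
  gp <- grid$points
  m <- length(gp)
  tol <- grid$step / 2
  span <- max(gp) - min(gp)

  log_rows <- vector("list", nrow(meals))
  curve_rows <- list()
  subj <- character(0); mealno <- integer(0)
  if (nrow(meals) == 0) {
    warning("No meals with label '", meal_label, "'; empty dataset.")
  }
  for (r in seq_len(nrow(meals))) {
    sid <- meals$subject_id[r]
    mt <- meals$meal_time[r]
    sel <- stream$subject_id == sid & !is.na(stream$glucose)
    st <- as.numeric(stream$time[sel])
    sg <- stream$glucose[sel]
    target <- as.numeric(mt) + gp * 60
    y <- snap_to_grid(st, sg, target, tol * 60)
    nobs <- sum(!is.na(y))
    gap_len <- max_na_run(y) * grid$step
    reason <- NA_character_
    if (nobs < min_prop_observed * m) {
      reason <- "too_few_observed"
    } else if (gap_len > max_internal_gap) {
      reason <- sprintf("gap_%g_min", gap_len)
    }
    kept <- is.na(reason)
    if (kept && anyNA(y)) y <- fill_short_gaps(y, gp)
    overlaps <- any(abs(as.numeric(meals$meal_time[meals$subject_id == sid]) -
                          as.numeric(mt)) < span * 60 &
                      meals$meal_time[meals$subject_id == sid] != mt)
    log_rows[[r]] <- tibble::tibble(
      subject_id = sid, meal_time = mt, n_observed = nobs,
      kept = kept, reason = reason, overlaps = overlaps)
    if (kept) {
      curve_rows[[length(curve_rows) + 1]] <- y
      subj <- c(subj, sid)
      mealno <- c(mealno, sum(subj == sid))
    }
  }
  if (!length(curve_rows)) {
    warning("No postprandial window survived the missingness policy.")
    Y <- matrix(numeric(0), 0, m)
    out <- structure(
      list(Y = Y, index = tibble::tibble(subject_id = character(),
                                         meal = integer()),
           grid = grid, n = 0L, J = integer(0)),
      class = "ppg_data")
  } else {
    out <- new_ppg_data(do.call(rbind, curve_rows), subj, mealno, grid)
  }
  attr(out, "window_log") <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble::tibble(subject_id = character(), meal_time = as.POSIXct(character()),
                   n_observed = integer(), kept = logical(),
                   reason = character(), overlaps = logical())
  out
}

#' Window extraction log
#'
#' @param data A [ppg_data()] produced by [extract_windows()].
#' @return The per-candidate-meal log tibble.
#' @export
window_log <- function(data) {
  attr(data, "window_log")
}

# Nearest-observation snapping: for each target time, the observation within
# +/- tol seconds, ties broken toward the later (post-meal) sample.
snap_to_grid <- function(obs_times, obs_values, targets, tol_sec) {
  out <- rep(NA_real_, length(targets))
  if (!length(obs_times)) return(out)
  pos <- findInterval(targets, obs_times)
  for (k in seq_along(targets)) {
    cand <- c(pos[k], pos[k] + 1)
    cand <- cand[cand >= 1 & cand <= length(obs_times)]
    if (!length(cand)) next
    d <- abs(obs_times[cand] - targets[k])
    keep <- which(d <= tol_sec + 1e-9)
    if (!length(keep)) next
    # ties toward the later sample: among minimal distances pick max time
    dmin <- min(d[keep])
    best <- cand[keep][d[keep] <= dmin + 1e-9]
    out[k] <- obs_values[max(best)]
  }
  out
}

max_na_run <- function(y) {
  if (!anyNA(y)) return(0L)
  r <- rle(is.na(y))
  max(r$lengths[r$values])
}

fill_short_gaps <- function(y, t) {
  filled <- stats::approx(t[!is.na(y)], y[!is.na(y)], xout = t,
                          method = "linear", rule = 2)$y
  ifelse(is.na(y), filled, y)
}

#' Pre-meal baseline glucose
#'
#' The observation nearest to `meal_time - 5` minutes within +/- half the
#' cadence (2.5 min), ties broken toward the later sample; `NA` when no
#' observation qualifies.
#'
#' @param stream CGM stream tibble (one or more subjects).
#' @param meal_time POSIXct vector of meal times.
#' @param subject_id Subject of each meal (recycled if length 1).
#' @param cadence Nominal sampling cadence, minutes.
#' @return Numeric vector of baseline glucose values (mg/dL), `NA` where
#'   unavailable.
#' @export
baseline_glucose <- function(stream, meal_time, subject_id = NULL,
                             cadence = 5) {
  if (is.null(subject_id)) subject_id <- rep(unique(stream$subject_id)[1],
                                             length(meal_time))
  if (length(subject_id) == 1) subject_id <- rep(subject_id, length(meal_time))
  out <- rep(NA_real_, length(meal_time))
  for (sid in unique(subject_id)) {
    sel <- stream$subject_id == sid & !is.na(stream$glucose)
    which_m <- which(subject_id == sid)
    out[which_m] <- snap_to_grid(
      as.numeric(stream$time[sel]), stream$glucose[sel],
      as.numeric(meal_time[which_m]) - 5 * 60, cadence / 2 * 60)
  }
  out
}

#' Assemble the curve-aligned covariate table
#'
#' One covariate row per curve of `data`: intercept, subject-level fields
#' (age, weight, gender, HbA1c, glycemic group), meal-level nutrients
#' (carbohydrate, fat, protein, fiber grams) and the pre-meal baseline
#' glucose. Subject-level fields are constant within subject by
#' construction. Rows with a missing baseline are retained (the two-level
#' decomposition needs no covariates) but marked not regression-ready.
#'
#' @param data A [ppg_data()] from [extract_windows()] (its window log
#'   supplies the meal times).
#' @param subjects Subject table: `subject_id`, `age`, `weight`,
#'   `gender_male`, `hba1c`, `group`.
#' @param meals Meal log with nutrient columns.
#' @param baseline Optional numeric vector of pre-meal glucose per curve; if
#'   `NULL` it is looked up from `stream`.
#' @param stream Optional stream for baseline lookup.
#' @return Tibble with `subject_id`, `meal`, `intercept`, `age`, `weight`,
#'   `gender_male`, `hba1c`, `carbohydrates`, `fats`, `proteins`, `fiber`,
#'   `initial_glucose`, `group`, `fosr_ready`.
#' @export
attach_covariates <- function(data, subjects, meals, baseline = NULL,
                              stream = NULL) {
  log <- window_log(data)
  if (is.null(log)) stop("`data` lacks a window log; use extract_windows().",
                         call. = FALSE)
  kept <- log[log$kept, , drop = FALSE]
  stopifnot(nrow(kept) == nrow(data$Y))
  si <- match(data$index$subject_id, subjects$subject_id)
  if (anyNA(si)) {
    stop("Unresolvable subject record for row(s): ",
         paste(which(is.na(si)), collapse = ", "), call. = FALSE)
  }
  mi <- match(paste(kept$subject_id, kept$meal_time),
              paste(meals$subject_id, meals$meal_time))
  if (anyNA(mi)) {
    stop("Unresolvable meal record for row(s): ",
         paste(which(is.na(mi)), collapse = ", "), call. = FALSE)
  }
  if (is.null(baseline)) {
    if (is.null(stream)) stop("Supply `baseline` or `stream`.", call. = FALSE)
    baseline <- baseline_glucose(stream, kept$meal_time, kept$subject_id)
  }
  tibble::tibble(
    subject_id = data$index$subject_id,
    meal = data$index$meal,
    intercept = 1,
    age = subjects$age[si],
    weight = subjects$weight[si],
    gender_male = subjects$gender_male[si],
    hba1c = subjects$hba1c[si],
    carbohydrates = meals$carbohydrates[mi],
    fats = meals$fats[mi],
    proteins = meals$proteins[mi],
    fiber = meals$fiber[mi],
    initial_glucose = baseline,
    group = subjects$group[si],
    fosr_ready = !is.na(baseline)
  )
}
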