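#' Postprandial curve dataset
#'
#' Container for a set of postprandial glucose curves observed on a common
#' grid. Curves are indexed by subject and by a within-subject meal ordinal
#' (chronological order). Internally the curves live in a matrix with one row
#' per (subject, meal); [tidy.ppg_data()] returns the long tibble form.
#'
#' @param curves Either a numeric matrix (rows = curves, columns = grid
#'   points) or a long data frame with columns `subject_id`, `meal`,
#'   `t`, `glucose`.
#' @param subject Subject identifier per row (required for matrix input).
#' @param meal Within-subject meal ordinal per row (matrix input only;
#'   defaults to chronological order of appearance).
#' @param grid A `cgm_grid`; for long input defaults to the sorted unique
#'   `t` values.
#' @return An object of class `ppg_data` with elements `Y` (matrix),
#'   `index` (tibble: `subject_id`, `meal`), `grid`, `n` (number of
#'   subjects) and `J` (named vector of per-subject meal counts).
#' @export
ppg_data <- function(curves, subject = NULL, meal = NULL, grid = NULL) {
  if (is.data.frame(curves)) {
    df <- curves
    need <- c("subject_id", "meal", "t", "glucose")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("Long input lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(grid)) {
      tu <- sort(unique(df$t))
      step <- unique(round(diff(tu), 8))
      if (length(step) != 1) stop("Irregular `t` values; supply `grid`.",
                                  call. = FALSE)
      grid <- make_grid(min(tu), max(tu), step)
    }
    df <- dplyr::arrange(df, .data$subject_id, .data$meal, .data$t)
    key <- dplyr::distinct(df, .data$subject_id, .data$meal)
    m <- length(grid$points)
    if (nrow(df) != nrow(key) * m) {
      stop("Every (subject, meal) must be observed on the full grid.",
           call. = FALSE)
    }
    Y <- matrix(df$glucose, nrow = nrow(key), ncol = m, byrow = TRUE)
    return(new_ppg_data(Y, key$subject_id, key$meal, grid))
  }
  Y <- as.matrix(curves)
  if (is.null(subject)) stop("`subject` is required for matrix input.",
                             call. = FALSE)
  if (is.null(grid)) grid <- make_grid(0, (ncol(Y) - 1) * 5, 5)
  if (is.null(meal)) {
    meal <- stats::ave(seq_along(subject), subject, FUN = seq_along)
  }
  new_ppg_data(Y, subject, meal, grid)
}

new_ppg_data <- function(Y, subject, meal, grid) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == length(subject), length(meal) == length(subject))
  if (ncol(Y) != length(grid$points)) {
    stop("Curve length does not match the grid.", call. = FALSE)
  }
  ord <- order(subject, meal)
  Y <- Y[ord, , drop = FALSE]
  index <- tibble::tibble(subject_id = subject[ord], meal = as.integer(meal[ord]))
  J <- table(index$subject_id)
  structure(
    list(
      Y = unname(Y),
      index = index,
      grid = grid,
      n = length(J),
      J = stats::setNames(as.integer(J), names(J))
    ),
    class = "ppg_data"
  )
}

#' @export
print.ppg_data <- function(x, ...) {
  cat("<ppg_data> ", nrow(x$Y), " curves from ", x$n, " subjects on ",
      length(x$grid$points), "-point grid [", min(x$grid$points), ", ",
      max(x$grid$points), "] min\n", sep = "")
  invisible(x)
}

#' @export
dim.ppg_data <- function(x) dim(x$Y)

#' Long-tibble view of a curve dataset
#'
#' @param x A `ppg_data`.
#' @param ... Unused.
#' @return Tibble with columns `subject_id`, `meal`, `t`, `glucose`,
#'   one row per observed point.
#' @export
tidy.ppg_data <- function(x, ...) {
  m <- length(x$grid$points)
  tibble::tibble(
    subject_id = rep(x$index$subject_id, each = m),
    meal = rep(x$index$meal, each = m),
    t = rep(x$grid$points, times = nrow(x$Y)),
    glucose = as.vector(t(x$Y))
  )
}

# Row indices grouped by subject, in index order.
subject_rows <- function(data) {
  split(seq_len(nrow(data$Y)), data$index$subject_id)
}
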