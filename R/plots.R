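#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot postprandial curves
#'
#' Spaghetti plot of the curves, one line per (subject, meal), coloured by
#' subject.
#'
#' @param data A [ppg_data()].
#' @param max_subjects Plot at most this many subjects.
#' @return A ggplot object.
#' @export
plot_curves <- function(data, max_subjects = 12) {
  long <- tidy.ppg_data(data)
  keep <- utils::head(unique(long$subject_id), max_subjects)
  long <- dplyr::filter(long, .data$subject_id %in% keep)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$t, y = .data$glucose,
    group = interaction(.data$subject_id, .data$meal),
    colour = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "Minutes since meal", y = "Glucose (mg/dL)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ppg_data <- function(object, ...) plot_curves(object, ...)

#' Plot estimated eigenfunctions of a two-level decomposition
#'
#' @param object An `mfpca_fit`.
#' @param ... Unused.
#' @return A ggplot object faceted by hierarchy level.
#' @export
autoplot.mfpca_fit <- function(object, ...) {
  df <- tidy.mfpca_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = "Minutes since meal", y = "Eigenfunction",
                  colour = "Component") +
    ggplot2::theme_minimal()
}

#' Plot coefficient functions with confidence bands
#'
#' Dashed point estimates with shaded joint bands and dotted null line,
#' one facet per term.
#'
#' @param object A `fosr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fosr_fit <- function(object, ...) {
  df <- tidy.fosr_fit(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$estimate))
  if ("joint_lo" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$joint_lo, ymax = .data$joint_hi),
      fill = "grey70", alpha = 0.6)
  }
  p +
    ggplot2::geom_line(linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Minutes since meal", y = "Coefficient (mg/dL per unit)") +
    ggplot2::theme_minimal()
}

#' Plot a pointwise R-squared curve
#'
#' @param object An `fr2_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fr2_result <- function(object, ...) {
  df <- tidy.fr2_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::labs(x = "Minutes since meal",
                  y = expression(R^2 ~ "(t)"),
                  title = object$variant) +
    ggplot2::theme_minimal()
}
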