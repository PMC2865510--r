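#' Plot a steady-state response curve
#'
#' Gata2 concentration against the signal, stable branches drawn solid
#' and unstable branches dotted, mirroring the conventional bifurcation
#' diagram of the triad.
#'
#' @param object A `triad_response` from [trace_response()].
#' @param var Which state variable to plot (`"x_g"` by default).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triad_response <- function(object, var = "x_g", ...) {
  df <- tidy(object)
  df$branch <- ifelse(df$stable, "stable", "unstable")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$signal,
                                        y = .data[[var]],
                                        linetype = .data$branch,
                                        shape = .data$branch)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dotted")) +
    ggplot2::labs(x = object$axis, y = var,
                  title = paste0("Steady-state response (",
                                 object$classification, ")")) +
    ggplot2::theme_minimal()
  if (object$axis != "eta") {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Plot a triad trajectory
#'
#' @param object A `triad_trajectory` from [integrate_triad()].
#' @param time_unit `"tau"` (dimensionless) or `"hours"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triad_trajectory <- function(object, time_unit = c("tau", "hours"),
                                      ...) {
  time_unit <- match.arg(time_unit)
  tcol <- if (time_unit == "tau") "time" else "hours"
  df <- tidyr::pivot_longer(object, c("x_s", "x_g", "x_f"),
                            names_to = "species", values_to = "x")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[tcol]], y = .data$x,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = time_unit, y = "dimensionless concentration") +
    ggplot2::theme_minimal()
}

#' Plot a minimum-pulse-duration filter curve
#'
#' @param object A `filter_curve` from [filter_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_curve <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, is.finite(.data$duration)),
                  ggplot2::aes(x = .data$amplitude, y = .data$hours)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pulse amplitude", y = "minimum pulse duration (h)",
                  title = paste("Low-pass filter curve:",
                                object$axis[1])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
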