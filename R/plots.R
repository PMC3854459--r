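#' Plot a simulated trace
#'
#' Cumulative capacitance (top) and pool occupancies (bottom) against
#' time, with the Ca2+ drive as a secondary panel caption.
#'
#' @param object A `pool_trace`.
#' @param pools Plot the pool occupancies too? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pool_trace
#' @export
autoplot.pool_trace <- function(object, pools = TRUE, ...) {
  pool_cols <- setdiff(names(object), c("t", "ca", "dCm", "influx"))
  long <- tidyr::pivot_longer(
    object[, c("t", "dCm", if (pools) pool_cols)],
    cols = -"t", names_to = "series", values_to = "fF")
  long$panel <- ifelse(long$series == "dCm", "cumulative release", "pools")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$fF,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "capacitance (fF)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a burst decomposition over its data
#'
#' @param object A `burst_fit`.
#' @param ... Unused.
#' @return A ggplot with the trace, the fitted model, and the sustained
#'   component shown separately.
#' @method autoplot burst_fit
#' @export
autoplot.burst_fit <- function(object, ...) {
  d <- object$data
  d$sustained <- object$A0 + object$A3 * (d$t - object$t0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$dCm), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "blue",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sustained), colour = "red",
                       linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "cumulative release (fF)",
                  subtitle = sprintf(
                    "fast: %.3g fF @ %.3g /s; slow: %.3g fF @ %.3g /s; sustained %.3g fF/s",
                    object$A1, object$rate_fast, object$A2, object$rate_slow,
                    object$A3)) +
    ggplot2::theme_minimal()
}

#' Plot a scan result
#'
#' @param object A `pool_scan`.
#' @param y Columns to display (default the burst rates or amplitudes
#'   present in the scan).
#' @param ... Unused.
#' @return A ggplot of the selected series against the scan's
#'   independent variable.
#' @method autoplot pool_scan
#' @export
autoplot.pool_scan <- function(object, y = NULL, ...) {
  xvar <- attr(object, "independent")
  if (is.null(y))
    y <- intersect(c("rate_fast", "rate_slow", "A_fast", "A_slow",
                     "A1", "A2", "fast_fraction", "recovery_fast",
                     "recovery_slow", "tau_fast", "tau_slow"),
                   names(object))
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c(xvar, y)],
                              cols = -dplyr::all_of(xvar),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xvar, colour = NULL) +
    ggplot2::theme_minimal()
}
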