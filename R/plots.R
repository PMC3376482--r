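#' @importFrom ggplot2 autoplot ggplot aes geom_line facet_wrap labs
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot a volume trajectory
#'
#' Per-compartment volume and flow against time, plus the summed (total)
#' signals.
#'
#' @param object a `lung_trajectory`.
#' @param what `"volume"`, `"flow"` or `"acceleration"`.
#' @param total overlay the sum across compartments?
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lung_trajectory <- function(object,
                                     what = c("volume", "flow", "acceleration"),
                                     total = TRUE, ...) {
  what <- match.arg(what)
  df <- tidy(object)
  col <- switch(what, volume = "volume_l", flow = "flow_l_per_s",
                acceleration = "accel_l_per_s2")
  ylab <- switch(what, volume = "volume (l)", flow = "flow (l/s)",
                 acceleration = "acceleration (l/s²)")
  df$compartment <- factor(df$compartment)
  p <- ggplot(df, aes(x = .data$time_s, y = .data[[col]],
                      colour = .data$compartment)) +
    geom_line() +
    labs(x = "time (s)", y = ylab, colour = "compartment") +
    theme_minimal()
  if (total && object$m > 1L) {
    tot <- tibble::tibble(
      time_s = object$time,
      value = rowSums(switch(what, volume = object$x, flow = object$dx,
                             acceleration = object$ddx)))
    p <- p + geom_line(data = tot, aes(x = .data$time_s, y = .data$value),
                       inherit.aes = FALSE, linewidth = 0.9)
  }
  p
}

#' Plot a reconstructed pressure trace
#'
#' @param object a `pressure_trace`.
#' @param ... unused.
#' @return a ggplot object with per-compartment pressures and the consensus.
#' @export
autoplot.pressure_trace <- function(object, ...) {
  df <- tidy(object)
  df$compartment <- factor(df$compartment)
  ggplot(df, aes(x = .data$time_s, y = .data$pressure_cmH2O,
                 colour = .data$compartment)) +
    geom_line() +
    geom_line(aes(y = .data$consensus), colour = "black", linetype = 2) +
    labs(x = "time (s)", y = "driving pressure (cmH2O)",
         colour = "compartment") +
    theme_minimal()
}

#' Plot a full breathing cycle
#'
#' @param object a `breath_cycle`.
#' @param ... passed to [autoplot.lung_trajectory()].
#' @return a ggplot object.
#' @export
autoplot.breath_cycle <- function(object, ...) {
  autoplot(object$trajectory, ...)
}

#' @importFrom rlang .data
NULL
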