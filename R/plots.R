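#' Plot stream chemistry time series
#'
#' One panel per solute: stream concentration against time, with discharge
#' as context in the top panel.
#'
#' @param object An `rt_simoutput`.
#' @param solutes Stream columns to draw (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_simoutput <- function(object, solutes = NULL, ...) {
  d <- tidy(object)
  if (!is.null(solutes)) d <- d[d$solute %in% solutes, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$conc)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~solute, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = "stream concentration (mol/L)") +
    ggplot2::theme_minimal()
}

#' Plot a hydrology series
#'
#' Stacked panels of precipitation, snow water equivalent and the three flow
#' paths.
#'
#' @param object An `rt_hydro`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_hydro <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$variable %in% c("precip", "swe", "q_sf", "q_sz", "q_dz"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = "mm or mm/day") +
    ggplot2::theme_minimal()
}

#' Concentration-discharge plot
#'
#' log-log scatter of stream concentration against discharge with the fitted
#' power-law slope from [cq_summary()].
#'
#' @param out An `rt_simoutput`.
#' @param solute Stream column name.
#' @return A ggplot.
#' @export
plot_cq <- function(out, solute) {
  s <- cq_summary(out, solute)
  d <- out$stream[is.finite(out$stream$q) & out$stream$q > 0, ]
  d <- d[is.finite(d[[solute]]) & d[[solute]] > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data[[solute]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "discharge (mm/day)", y = paste(solute, "(mol/L)"),
                  title = sprintf("%s: slope %.2f, Spearman rho %.2f",
                                  solute, s$slope, s$rho)) +
    ggplot2::theme_minimal()
}

#' Plot per-zone reaction rates
#'
#' @param out An `rt_simoutput`.
#' @return A ggplot of time-averaged daily reaction rates (mmol/m2/day),
#'   faceted by zone.
#' @export
plot_rates <- function(out) {
  ggplot2::ggplot(out$rates,
                  ggplot2::aes(x = .data$date, y = .data$rate_mmol_m2_day,
                               colour = .data$reaction)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~zone, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "day", y = "rate (mmol/m2/day)") +
    ggplot2::theme_minimal()
}
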