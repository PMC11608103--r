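#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation output
#'
#' Long tibble of stream concentrations: one row per day and solute.
#'
#' @param x An `rt_simoutput`.
#' @param ... Unused.
#' @return A tibble: `date`, `q`, `solute`, `conc`.
#' @export
tidy.rt_simoutput <- function(x, ...) {
  tidyr::pivot_longer(x$stream, cols = -c("date", "q"),
                      names_to = "solute", values_to = "conc")
}

#' One-row summary of a simulation
#'
#' @param x An `rt_simoutput`.
#' @param ... Unused.
#' @return A tibble: days simulated, mean discharge, flow-path fractions and
#'   the worst conservative budget residual.
#' @export
glance.rt_simoutput <- function(x, ...) {
  h <- x$hydro
  tibble(n_days = nrow(h),
         mean_q = mean(h$q),
         frac_q_sf = sum(h$q_sf) / sum(h$q),
         frac_q_sz = sum(h$q_sz) / sum(h$q),
         frac_q_dz = sum(h$q_dz) / sum(h$q),
         n_solutes = ncol(x$stream) - 2)
}

#' Tidy a hydrology series
#'
#' @param x An `rt_hydro`.
#' @param ... Unused.
#' @return Long tibble: `date`, `variable`, `value`.
#' @export
tidy.rt_hydro <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = -"date",
                      names_to = "variable", values_to = "value")
}

#' @export
glance.rt_hydro <- function(x, ...) {
  tibble(n_days = nrow(x),
         total_precip = sum(x$precip),
         total_aet = sum(x$aet),
         total_q = sum(x$q),
         frac_q_sf = sum(x$q_sf) / sum(x$q),
         frac_q_sz = sum(x$q_sz) / sum(x$q),
         frac_q_dz = sum(x$q_dz) / sum(x$q))
}
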