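#' Synthetic climate specification
#'
#' Parameters of the stochastic daily weather generator: sinusoidal annual
#' temperature cycle with Gaussian day-to-day noise, Bernoulli wet-day
#' occurrence with a mild summer-weighted seasonality, gamma-distributed wet-day
#' intensity, and a temperature-indexed potential evapotranspiration model
#' `pet = pet_coeff * max(temp, 0)`.
#'
#' @param mean_annual_precip Target mean annual precipitation, mm.
#' @param temp_mean Mean annual temperature, degC.
#' @param temp_amplitude Seasonal temperature amplitude, degC.
#' @param temp_sd Day-to-day temperature noise, degC.
#' @param wet_prob Mean wet-day probability.
#' @param wet_seasonality Relative summer weighting of wet-day probability
#'   (0 = uniform).
#' @param gamma_shape Gamma shape of wet-day precipitation intensity.
#' @param pet_coeff PET per degree above freezing, mm/day/degC.
#' @param snow_temp Rain/snow threshold used for snow-fraction reporting, degC.
#' @param chem Named precipitation chemistry concentrations, mol/L
#'   (constant in time).
#' @return A `climate_spec` list.
#' @export
climate_spec <- function(mean_annual_precip = 1320, temp_mean = 5,
                         temp_amplitude = 11, temp_sd = 3.5,
                         wet_prob = 0.45, wet_seasonality = 0.35,
                         gamma_shape = 0.7, pet_coeff = 0.25,
                         snow_temp = 0, chem = numeric(0)) {
  stopifnot(mean_annual_precip > 0, temp_amplitude > 0, temp_sd >= 0,
            wet_prob > 0, wet_prob <= 1, wet_seasonality >= 0,
            wet_seasonality < 1, gamma_shape > 0, pet_coeff >= 0)
  structure(list(mean_annual_precip = mean_annual_precip,
                 temp_mean = temp_mean, temp_amplitude = temp_amplitude,
                 temp_sd = temp_sd, wet_prob = wet_prob,
                 wet_seasonality = wet_seasonality, gamma_shape = gamma_shape,
                 pet_coeff = pet_coeff, snow_temp = snow_temp, chem = chem),
            class = "climate_spec")
}

#' Humid continental, seasonally snow-influenced climate preset
#'
#' Defaults emulating a small New England headwater catchment: ~1320 mm/yr
#' precipitation, mean annual temperature ~5 degC, with 20-30% of
#' precipitation falling as snow and a spring snowmelt discharge peak.
#'
#' @param chem Named precipitation chemistry, mol/L.
#' @return A [climate_spec()].
#' @export
w9_climate <- function(chem = numeric(0)) {
  climate_spec(chem = chem)
}

#' Generate synthetic daily forcing
#'
#' Draws a reproducible daily weather series from a [climate_spec()]:
#' temperature follows a sinusoid with minimum in late January plus Gaussian
#' noise; precipitation occurrence is Bernoulli with the wet-day probability
#' modulated by season (summer-weighted), intensity is gamma with mean set so
#' annual precipitation hits the spec target; PET is temperature-indexed.
#' Precipitation chemistry columns (`chem_<species>`) are constant.
#'
#' @param n_days Number of days (>= 365).
#' @param spec A [climate_spec()].
#' @param seed Integer seed; the same spec and seed give an identical series.
#' @return A forcing tibble: `date` (1..n), `precip`, `temp`, `pet`,
#'   `chem_*` columns.
#' @export
generate_forcing <- function(n_days, spec = w9_climate(), seed = 1) {
  stopifnot(inherits(spec, "climate_spec"))
  if (n_days < 365) stopf("n_days must be >= 365")
  day <- seq_len(n_days)
  # seasonal phase: minimum temperature near day 25 (late January)
  phase <- 2 * pi * (day - 25 - 365 / 4) / 365
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    temp <- spec$temp_mean + spec$temp_amplitude * sin(phase) +
      stats::rnorm(n_days, 0, spec$temp_sd)
    p_wet <- spec$wet_prob * (1 + spec$wet_seasonality * sin(phase))
    wet <- stats::rbinom(n_days, 1, pmin(pmax(p_wet, 0), 1))
    mean_wet_days <- spec$wet_prob * 365
    mean_intensity <- spec$mean_annual_precip / mean_wet_days
    precip <- wet * stats::rgamma(n_days, shape = spec$gamma_shape,
                                  scale = mean_intensity / spec$gamma_shape)
  })
  pet <- spec$pet_coeff * pmax(temp, 0)
  out <- tibble(date = day, precip = precip, temp = temp, pet = pet)
  for (s in names(spec$chem)) out[[paste0("chem_", s)]] <- spec$chem[[s]]
  out
}

#' Snow fraction of a forcing series
#'
#' Share of total precipitation falling on days with temperature at or below
#' the rain/snow threshold.
#'
#' @param forcing Forcing tibble.
#' @param snow_temp Threshold, degC.
#' @return Fraction in \[0, 1\].
#' @export
snow_fraction <- function(forcing, snow_temp = 0) {
  sum(forcing$precip[forcing$temp <= snow_temp]) / sum(forcing$precip)
}
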