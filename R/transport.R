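#' Flux-weighted infiltration concentration
#'
#' Concentration of water infiltrating the shallow zone: the flux-weighted
#' mean of rain and snowmelt chemistry,
#' `(p_rain * c_rain + q_melt * c_melt) / (p_rain + q_melt)`; defined as 0
#' when both fluxes are 0.
#'
#' @param p_rain Rainfall, mm/day.
#' @param c_rain Rain concentration(s), mol/L (scalar or named vector).
#' @param q_melt Snowmelt, mm/day.
#' @param c_melt Snowmelt concentration(s), mol/L.
#' @return Concentration(s), mol/L.
#' @export
infiltration_concentration <- function(p_rain, c_rain, q_melt, c_melt) {
  if (p_rain < 0 || q_melt < 0) stopf("negative water fluxes")
  tot <- p_rain + q_melt
  if (tot == 0) return(c_rain * 0)
  (p_rain * c_rain + q_melt * c_melt) / tot
}

#' Snowpack chemistry state
#'
#' @param swe Snow water equivalent, mm.
#' @param conc Named species concentrations in the pack, mol/L.
#' @return An object of class `rt_snow_chem`.
#' @export
snow_chem_state <- function(swe = 0, conc = numeric(0)) {
  stopifnot(swe >= 0)
  structure(list(swe = swe, conc = conc), class = "rt_snow_chem")
}

#' Advance snowpack chemistry by one step
#'
#' Mass balance of solutes in the snow store: snowfall adds solute at
#' precipitation-chemistry concentration; melt exports at pack concentration
#' (melt has the same chemistry as the pack, which is updated by snowfall
#' mixing before melt leaves). No reactions occur in the pack.
#'
#' @param s An [snow_chem_state()].
#' @param p_snow Snowfall, mm/day.
#' @param c_ppt Precipitation chemistry, named mol/L.
#' @param q_melt Snowmelt, mm/day.
#' @param dt Step, days.
#' @return A list: `state` (updated pack) and `c_melt` (melt concentration,
#'   mol/L).
#' @export
step_snow_chemistry <- function(s, p_snow, c_ppt, q_melt, dt = 1) {
  stopifnot(inherits(s, "rt_snow_chem"), p_snow >= 0, q_melt >= 0, dt > 0)
  swe_in <- s$swe + p_snow * dt
  if (q_melt * dt > swe_in + 1e-9)
    stopf("snowmelt (%g mm) exceeds available snow water (%g mm)",
          q_melt * dt, swe_in)
  conc <- expand_named(s$conc, names(c_ppt))
  mass <- conc * s$swe + c_ppt * p_snow * dt
  c_pack <- if (swe_in > 0) mass / swe_in else conc * 0
  swe_out <- max(swe_in - q_melt * dt, 0)
  mass_out <- mass - c_pack * q_melt * dt
  state <- snow_chem_state(swe = swe_out,
                           conc = if (swe_out > 0) mass_out / swe_out
                                  else c_pack * 0)
  list(state = state, c_melt = c_pack)
}

# mobile/immobile split of component totals: immobile species are the
# sorption-site primaries and any secondary with an immobile phase
mobile_mask <- function(eqsys) {
  ph <- eqsys$species
  prim_mobile <- ph$mobile[match(eqsys$primaries, ph$name)]
  sec_mobile <- ph$mobile[match(eqsys$secondaries, ph$name)]
  list(prim = stats::setNames(prim_mobile, eqsys$primaries),
       sec = stats::setNames(sec_mobile, eqsys$secondaries))
}

# mobile part of each component total (mol/L), given a speciated state
mobile_totals <- function(state) {
  sys <- state$sys
  mm <- mobile_mask(sys)
  tot <- ifelse(mm$prim, state$conc[sys$primaries], 0)
  names(tot) <- sys$primaries
  if (length(sys$secondaries)) {
    cs <- state$conc[sys$secondaries] * as.numeric(mm$sec)
    tot <- tot + as.numeric(crossprod(sys$tableau, cs))
  }
  tot
}

#' Advect solutes through the zone cascade for one step
#'
#' Fully implicit (backward Euler) update of the mobile solute mass in the
#' surface, shallow and deep zones, in cascade order: rain and snowmelt mix
#' into the surface zone, infiltration (at the rain/melt flux-weighted
#' concentration) enters the shallow zone, percolation carries end-of-step
#' shallow-zone concentration into the deep zone, and each zone exports at its
#' own end-of-step concentration. Evapotranspiration removes water only
#' (solutes are concentrated by the storage change). Immobile species
#' (sorption sites and sorbed mass) are retained in place. Reactions are not
#' applied here (operator splitting: transport first, then zone kinetics).
#'
#' @param states List with elements `snow` ([snow_chem_state()]) and `SF`,
#'   `SZ`, `DZ` ([zone_chem_state()]).
#' @param hydro One day of hydrology: a list/row with `p_snow`, `rain`,
#'   `snowmelt`, `q_sf`, `q_infil`, `q_sz`, `q_perc`, `q_dz`, and end-of-step
#'   storages `v_sf`, `v_sz`, `v_dz` (mm).
#' @param c_rain Precipitation chemistry, named mol/L over mobile primaries.
#' @param dt Step, days.
#' @return A list: `states` (updated), `c_melt`, `c_infil`, and `exports`
#'   (list of per-zone export concentrations at end of step).
#' @export
step_zone_advection <- function(states, hydro, c_rain, dt = 1) {
  sn <- step_snow_chemistry(states$snow, hydro$p_snow, c_rain,
                            hydro$snowmelt, dt)
  c_melt <- expand_named(sn$c_melt, names(c_rain))
  c_infil <- infiltration_concentration(hydro$rain, c_rain,
                                        hydro$snowmelt, c_melt)

  advect <- function(zc, v_new, influx, q_out) {
    # influx: named solute flux (mol/m2/day); q_out: total outflow (mm/day)
    prim <- names(zc$totals)
    if (!is.null(zc$eqsys) && !is.null(zc$speciated)) {
      mob <- mobile_totals(zc$speciated)
      imm_mass <- (zc$totals - mob) * zc$v_w
    } else {
      mob <- zc$totals
      imm_mass <- zc$totals * 0
    }
    m_old <- mob * zc$v_w
    c_new <- (m_old + expand_named(influx, prim) * dt) / (v_new + q_out * dt)
    neg <- c_new < 0
    if (any(neg)) {
      warnf("negative end-of-step concentration in zone %s; clipped", zc$zone)
      c_new[neg] <- 1e-20
    }
    zc$totals <- c_new + imm_mass / v_new
    zc$v_w <- v_new
    if (!is.null(zc$eqsys))
      zc$speciated <- speciate(zc$totals, zc$eqsys,
                               init = zc$speciated$log10_prim)
    list(zc = zc, c_out = c_new)
  }

  sf <- advect(states$SF, hydro$v_sf,
               influx = hydro$rain * c_rain + hydro$snowmelt * c_melt -
                 hydro$q_infil * c_infil,
               q_out = hydro$q_sf)
  sz <- advect(states$SZ, hydro$v_sz,
               influx = hydro$q_infil * c_infil,
               q_out = hydro$q_sz + hydro$q_perc)
  dz <- advect(states$DZ, hydro$v_dz,
               influx = hydro$q_perc * sz$c_out,
               q_out = hydro$q_dz)

  list(states = list(snow = sn$state, SF = sf$zc, SZ = sz$zc, DZ = dz$zc),
       c_melt = c_melt, c_infil = c_infil,
       exports = list(SF = sf$c_out, SZ = sz$c_out, DZ = dz$c_out))
}

#' Flux-weighted stream concentration
#'
#' Instantaneous mixing of the three flow paths at the outlet:
#' `(q_sf*c_sf + q_sz*c_sz + q_dz*c_dz) / (q_sf + q_sz + q_dz)`. Days with no
#' flow are reported as `NA`.
#'
#' @param q_sf,q_sz,q_dz Path flows, mm/day.
#' @param c_sf,c_sz,c_dz Path concentrations, mol/L.
#' @return Stream concentration, mol/L (or `NA` on zero-flow days).
#' @export
stream_concentration <- function(q_sf, q_sz, q_dz, c_sf, c_sz, c_dz) {
  if (any(c(q_sf, q_sz, q_dz) < 0)) stopf("negative flow")
  qt <- q_sf + q_sz + q_dz
  if (qt == 0) return(c_sf * NA_real_)
  (q_sf * c_sf + q_sz * c_sz + q_dz * c_dz) / qt
}
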