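#' HBV bucket-model parameters
#'
#' Parameters of the standard single-column HBV structure: degree-day snow
#' routine, soil-moisture accounting with beta-function recharge, a two-outlet
#' upper zone and a linear-reservoir lower zone.
#'
#' @param tt Rain/snow threshold temperature, degC.
#' @param cfmax Degree-day melt factor, mm/degC/day.
#' @param fc Field capacity of the soil store, mm.
#' @param lp Fraction of `fc` above which evapotranspiration is potential.
#' @param beta Recharge nonlinearity exponent.
#' @param k0,k1,k2 Recession coefficients (1/day) of quick flow, shallow
#'   lateral flow and deep groundwater flow; `k0 >= k1 >= k2`.
#' @param uzl Upper-zone threshold storage for quick flow, mm.
#' @param perc Maximum percolation (recharge to the deep store), mm/day.
#' @return An object of class `hbv_params`.
#' @export
hbv_params <- function(tt = 0, cfmax = 3.5, fc = 250, lp = 0.7, beta = 2,
                       k0 = 0.3, k1 = 0.1, k2 = 0.01, uzl = 20, perc = 2.5) {
  p <- list(tt = tt, cfmax = cfmax, fc = fc, lp = lp, beta = beta,
            k0 = k0, k1 = k1, k2 = k2, uzl = uzl, perc = perc)
  num <- unlist(p[c("cfmax", "fc", "lp", "beta", "k0", "k1", "k2", "uzl", "perc")])
  if (any(num < 0)) stopf("HBV parameters must be non-negative")
  if (!(k0 >= k1 && k1 >= k2)) stopf("HBV requires k0 >= k1 >= k2")
  if (k0 + k1 > 1) stopf("k0 + k1 must be <= 1 for a stable daily step")
  structure(p, class = "hbv_params")
}

#' Run the HBV bucket hydrology model
#'
#' Daily simulation of the standard HBV structure: snow accumulation and
#' degree-day melt, soil-moisture accounting with `(SM/FC)^beta` recharge
#' partitioning and soil-moisture-limited evapotranspiration, an upper store
#' with capped percolation and two linear outlets (quick flow above the
#' threshold `uzl`, shallow lateral flow), and a lower store draining as deep
#' groundwater flow. Every store's daily water balance closes exactly.
#'
#' For the reactive-transport zones the series also carries the infiltration
#' flux `q_infil = rain + snowmelt - q_sf` (water entering the shallow zone
#' after quick surface flow is removed; `q_sf` is capped at same-day
#' rain + melt so the transient surface store never goes negative) and the
#' percolation flux `q_perc` recharging the deep zone.
#'
#' @param forcing A forcing tibble (see [generate_forcing()] /
#'   [read_forcing()]) with columns `date`, `precip`, `temp`, `pet`.
#' @param params An [hbv_params()] object.
#' @param init Optional named list of initial stores (`swe`, `sm`, `uz`, `lz`),
#'   mm; defaults are 0, fc/2, 0, 100.
#' @return A tibble of class `rt_hydro` with daily stores and fluxes (mm,
#'   mm/day): `swe`, `snowmelt`, `rain`, `p_snow`, `sm`, `uz`, `lz`, `aet`,
#'   `q_sf`, `q_sz`, `q_dz`, `q`, `q_infil`, `q_perc`.
#' @export
run_hbv <- function(forcing, params = hbv_params(), init = list()) {
  stopifnot(inherits(params, "hbv_params"))
  need <- c("date", "precip", "temp", "pet")
  if (!all(need %in% names(forcing)))
    stopf("forcing lacks columns: %s",
          paste(setdiff(need, names(forcing)), collapse = ", "))
  if (any(forcing$precip < 0) || any(forcing$pet < 0))
    stopf("negative precipitation or PET in forcing")
  n <- nrow(forcing)
  P <- forcing$precip; Tm <- forcing$temp; PET <- forcing$pet
  swe <- sm <- uz <- lz <- aet <- numeric(n)
  melt <- rain <- psnow <- q0 <- q1 <- q2 <- qperc <- numeric(n)
  s_swe <- init$swe %||% 0
  s_sm <- init$sm %||% (params$fc / 2)
  s_uz <- init$uz %||% 0
  s_lz <- init$lz %||% 100
  for (t in seq_len(n)) {
    # snow routine
    if (Tm[t] <= params$tt) {
      psnow[t] <- P[t]; rain[t] <- 0
    } else {
      psnow[t] <- 0; rain[t] <- P[t]
    }
    s_swe <- s_swe + psnow[t]
    melt[t] <- if (Tm[t] > params$tt)
      min(s_swe, params$cfmax * (Tm[t] - params$tt)) else 0
    s_swe <- s_swe - melt[t]
    swe[t] <- s_swe
    # soil routine
    inflow <- rain[t] + melt[t]
    rech <- inflow * min(1, s_sm / params$fc)^params$beta
    s_sm <- s_sm + inflow - rech
    if (s_sm > params$fc) {        # overspill above field capacity
      rech <- rech + (s_sm - params$fc)
      s_sm <- params$fc
    }
    aet[t] <- min(s_sm, PET[t] * min(1, s_sm / (params$fc * params$lp)))
    s_sm <- s_sm - aet[t]
    sm[t] <- s_sm
    # upper zone
    s_uz <- s_uz + rech
    qperc[t] <- min(params$perc, s_uz)
    s_uz <- s_uz - qperc[t]
    # quick (surface) flow is routed through the transient surface store,
    # which is fed only by same-day rain + melt: cap q0 at that inflow so
    # every zone's balance closes; the upper store retains the remainder
    q0[t] <- min(params$k0 * max(s_uz - params$uzl, 0), inflow)
    q1[t] <- params$k1 * s_uz
    s_uz <- s_uz - q0[t] - q1[t]
    uz[t] <- s_uz
    # lower zone
    s_lz <- s_lz + qperc[t]
    q2[t] <- params$k2 * s_lz
    s_lz <- s_lz - q2[t]
    lz[t] <- s_lz
  }
  q_sf <- q0
  tibble(date = forcing$date, precip = P, temp = Tm, pet = PET,
         p_snow = psnow, rain = rain, snowmelt = melt, swe = swe,
         sm = sm, uz = uz, lz = lz, aet = aet,
         q_sf = q_sf, q_sz = q1, q_dz = q2, q = q_sf + q1 + q2,
         q_infil = rain + melt - q_sf, q_perc = qperc) |>
    structure(class = c("rt_hydro", "tbl_df", "tbl", "data.frame"))
}

#' Zone configuration
#'
#' Geometry and storage parameters of the three reactive-transport zones.
#'
#' @param sf_storage Transient surface-zone mixing storage, mm.
#' @param sz_depth,dz_depth Zone thickness, m.
#' @param sz_porosity,dz_porosity Porosity, fraction in (0, 1].
#' @param sz_passive,dz_passive Passive water storage, mm (water that does not
#'   generate streamflow but participates in mixing, reactions and ET).
#' @param fc Field capacity used to scale shallow-zone saturation, mm
#'   (defaults to the HBV `fc`).
#' @return A `zone_config` list.
#' @export
zone_config <- function(sf_storage = 5, sz_depth = 2, sz_porosity = 0.45,
                        sz_passive = 200, dz_depth = 6, dz_porosity = 0.2,
                        dz_passive = 500, fc = 250) {
  stopifnot(sf_storage > 0, sz_depth > 0, dz_depth > 0,
            sz_porosity > 0, sz_porosity <= 1,
            dz_porosity > 0, dz_porosity <= 1,
            sz_passive >= 0, dz_passive >= 0, fc > 0)
  structure(list(sf_storage = sf_storage, sz_depth = sz_depth,
                 sz_porosity = sz_porosity, sz_passive = sz_passive,
                 dz_depth = dz_depth, dz_porosity = dz_porosity,
                 dz_passive = dz_passive, fc = fc), class = "zone_config")
}

#' Derive per-zone hydrology for the reactive-transport step
#'
#' Maps HBV stores onto the three reactive-transport zones: shallow-zone
#' storage is upper-zone dynamic storage plus soil moisture plus passive
#' storage; deep-zone storage is lower-zone dynamic storage plus passive
#' storage; the surface zone carries a small transient mixing storage.
#' Saturations and water-table depths: `sw(SZ) = min(1, sm/fc)`,
#' `sw(DZ) = min(1, v_w / (porosity * depth))`,
#' `zw = max(0, depth - (v_w/1000) / porosity)` (m below ground of the zone
#' column; 0 when the pore space is full).
#'
#' @param h An `rt_hydro` tibble from [run_hbv()] or [read_hbv_light()].
#' @param zones A [zone_config()].
#' @return A tibble of class `rt_zone_hydro`, long over `zone` (SF/SZ/DZ) with
#'   `v_w` (mm), `sw`, `zw` (m) and the zone's in/outflow fluxes (mm/day).
#' @export
derive_zone_hydrology <- function(h, zones = zone_config()) {
  stopifnot(inherits(zones, "zone_config"))
  cap_sz <- zones$sz_porosity * zones$sz_depth * 1000
  cap_dz <- zones$dz_porosity * zones$dz_depth * 1000
  v_sz <- h$uz + h$sm + zones$sz_passive
  v_dz <- h$lz + zones$dz_passive
  if (any(v_sz > cap_sz) || any(v_dz > cap_dz))
    warnf("zone storage exceeds porosity*depth capacity on %d day(s); saturation capped at 1",
          sum(v_sz > cap_sz) + sum(v_dz > cap_dz))
  zw <- function(v, depth, poro) pmax(0, depth - (v / 1000) / poro)
  out <- dplyr::bind_rows(
    tibble(date = h$date, zone = "SF", v_w = zones$sf_storage,
           sw = 1, zw = 0,
           inflow = h$rain + h$snowmelt,
           outflow = h$q_sf + h$q_infil),
    tibble(date = h$date, zone = "SZ", v_w = v_sz,
           sw = pmin(1, h$sm / zones$fc),
           zw = zw(v_sz, zones$sz_depth, zones$sz_porosity),
           inflow = h$q_infil,
           outflow = h$q_sz + h$q_perc + h$aet),
    tibble(date = h$date, zone = "DZ", v_w = v_dz,
           sw = pmin(1, v_dz / cap_dz),
           zw = zw(v_dz, zones$dz_depth, zones$dz_porosity),
           inflow = h$q_perc,
           outflow = h$q_dz))
  structure(out, class = c("rt_zone_hydro", class(tibble())))
}
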