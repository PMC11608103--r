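#' Simulation configuration
#'
#' Bundles everything one run needs: forcing (a tibble or a synthetic-climate
#' recipe), hydrology (internal bucket-model parameters or HBV-light-style
#' files), zone geometry, the reaction network, initial conditions and
#' options.
#'
#' @param network An `rt_network`.
#' @param forcing A forcing tibble, or a list
#'   `list(source = "synthetic", spec = climate_spec(), years = 2)`.
#' @param hbv An [hbv_params()], or a list `list(results =, params =)` of
#'   HBV-light-style file paths.
#' @param zones A [zone_config()].
#' @param initial Named list of per-zone initial component totals (mol/L):
#'   elements `SF`, `SZ`, `DZ`, optionally `snow`.
#' @param precip_chem Named precipitation chemistry (mol/L), used for species
#'   without a `chem_` column in the forcing.
#' @param dt Time step, days (1 or an integer fraction of a day).
#' @param spinup_days Days of spin-up: the first `spinup_days` of forcing are
#'   run once, unrecorded, to damp initial-condition transients.
#' @param seed Seed for synthetic forcing.
#' @param surface_reactions Simulate reactions in the surface zone
#'   (off by default; quick flow has little contact time).
#' @param signed_q10 Use the signed Q10 exponent (see [env_factor_T()]).
#' @return An object of class `rt_sim_config`.
#' @export
sim_config <- function(network, forcing, hbv = hbv_params(),
                       zones = zone_config(), initial = list(),
                       precip_chem = numeric(0), dt = 1, spinup_days = 365,
                       seed = 1, surface_reactions = FALSE,
                       signed_q10 = FALSE) {
  stopifnot(inherits(network, "rt_network"), dt > 0)
  nsub <- round(1 / dt)
  if (abs(nsub * dt - 1) > 1e-9)
    stopf("dt must be 1 or an integer fraction of a day (got %g)", dt)
  structure(list(network = network, forcing = forcing, hbv = hbv,
                 zones = zones, initial = initial,
                 precip_chem = precip_chem, dt = dt,
                 spinup_days = spinup_days, seed = seed,
                 surface_reactions = surface_reactions,
                 signed_q10 = signed_q10), class = "rt_sim_config")
}

resolve_forcing <- function(cfg) {
  f <- cfg$forcing
  if (is.data.frame(f)) return(f)
  if (is.list(f) && identical(f$source, "synthetic")) {
    spec <- f$spec %||% w9_climate()
    return(generate_forcing(round((f$years %||% 2) * 365), spec,
                            seed = cfg$seed))
  }
  if (is.list(f) && !is.null(f$file)) return(read_forcing(f$file))
  stopf("cannot resolve forcing source")
}

resolve_hydro <- function(cfg, forcing) {
  h <- cfg$hbv
  if (inherits(h, "hbv_params")) return(run_hbv(forcing, h))
  if (is.list(h) && !is.null(h$results))
    return(read_hbv_light(h$results, h$params)$hydro)
  stopf("cannot resolve hydrology source")
}

#' Run a full reactive-transport simulation
#'
#' Orchestrates the sequential non-iterative (SNIA) loop: the bucket
#' hydrology is computed (or read) first; then, for every step, snowpack
#' chemistry and advective transport are advanced (backward Euler), followed
#' by the kinetic reaction step in each subsurface zone (Crank-Nicolson with
#' Newton-Raphson and adaptive step halving), with equilibrium speciation
#' closing each step. Deterministic given the configuration and seed.
#'
#' @param cfg An [sim_config()].
#' @return An object of class `rt_simoutput`: a list of tibbles `stream`
#'   (flux-weighted outlet concentrations, mol/L), `zones` (per-zone
#'   component totals, secondary-species concentrations and aggregates),
#'   `rates` (per-reaction time-averaged rates, mmol/m2/day), `exports`
#'   (per-zone solute export fluxes, mmol/m2/day), `stores` (solute store
#'   masses, mol/m2), `budget` (cumulative solute budget per component),
#'   plus `hydro` and the configuration.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "rt_sim_config"))
  forcing <- resolve_forcing(cfg)
  hydro <- resolve_hydro(cfg, forcing)
  if (nrow(hydro) != nrow(forcing))
    stopf("forcing and hydrology series lengths differ (%d vs %d)",
          nrow(forcing), nrow(hydro))
  zh <- derive_zone_hydrology(hydro, cfg$zones)
  v_sz <- zh$v_w[zh$zone == "SZ"]; sw_sz <- zh$sw[zh$zone == "SZ"]
  zw_sz <- zh$zw[zh$zone == "SZ"]
  v_dz <- zh$v_w[zh$zone == "DZ"]; sw_dz <- zh$sw[zh$zone == "DZ"]
  zw_dz <- zh$zw[zh$zone == "DZ"]
  v_sf <- zh$v_w[zh$zone == "SF"]

  net <- cfg$network
  eqsys <- net$eqsys
  prim <- eqsys$primaries
  aggs <- net$aggregates

  # precipitation chemistry: forcing columns override the config constants
  chem_f <- forcing_chem(forcing)
  c_rain_base <- expand_named(cfg$precip_chem, prim)
  rain_chem <- function(t) {
    c <- c_rain_base
    for (s in intersect(colnames(chem_f), prim)) c[s] <- chem_f[t, s]
    c
  }

  # pre-simulation storages, back-computed from the day-1 balances (which
  # close exactly), so the first step's implicit update is mass-consistent
  v0_sz <- v_sz[1] - (hydro$q_infil[1] - hydro$aet[1] - hydro$q_sz[1] -
                        hydro$q_perc[1])
  v0_dz <- v_dz[1] - (hydro$q_perc[1] - hydro$q_dz[1])

  init_state <- function(zone, v0) {
    zone_chem_state(zone, v0, expand_named(unlist(cfg$initial[[zone]]), prim),
                    eqsys, net$substrate_conc[[zone]] %||% list())
  }
  states <- list(
    snow = snow_chem_state(0, expand_named(unlist(cfg$initial$snow), prim)),
    SF = init_state("SF", v_sf[1]),
    SZ = init_state("SZ", v0_sz),
    DZ = init_state("DZ", v0_dz))

  rxn_zones <- c(if (cfg$surface_reactions) "SF", "SZ", "DZ")
  rids <- lapply(net$kinetic, function(l) vapply(l, `[[`, "", "id"))
  nsub <- round(1 / cfg$dt)
  n <- nrow(hydro)

  sec <- eqsys$secondaries
  mobp <- mobile_mask(eqsys)$prim

  # preallocated recorders
  rec_zone_tot <- list(SF = matrix(NA_real_, n, length(prim), dimnames = list(NULL, prim)),
                       SZ = matrix(NA_real_, n, length(prim), dimnames = list(NULL, prim)),
                       DZ = matrix(NA_real_, n, length(prim), dimnames = list(NULL, prim)))
  rec_zone_sec <- list(SF = matrix(NA_real_, n, length(sec), dimnames = list(NULL, sec)),
                       SZ = matrix(NA_real_, n, length(sec), dimnames = list(NULL, sec)),
                       DZ = matrix(NA_real_, n, length(sec), dimnames = list(NULL, sec)))
  rec_export <- rec_zone_tot
  all_rids <- unlist(rids[c("SF", "SZ", "DZ")])
  zone_of_rid <- rep(c("SF", "SZ", "DZ"), times = lengths(rids[c("SF", "SZ", "DZ")]))
  rec_rates <- matrix(0, n, length(all_rids),
                      dimnames = list(NULL, all_rids))
  rec_store <- matrix(NA_real_, n, length(prim), dimnames = list(NULL, prim))
  rec_input <- matrix(NA_real_, n, length(prim), dimnames = list(NULL, prim))
  rec_outflux <- matrix(NA_real_, n, length(prim), dimnames = list(NULL, prim))

  step_day <- function(states, t, record = FALSE) {
    c_rain <- rain_chem(t)
    h <- hydro[t, ]
    vs <- list(sf = v_sf[t], sz = v_sz[t], dz = v_dz[t])
    v_prev <- list(sf = states$SF$v_w, sz = states$SZ$v_w, dz = states$DZ$v_w)
    day_rates <- stats::setNames(numeric(length(all_rids)), all_rids)
    exp_acc <- expand_named(numeric(0), prim)
    for (k in seq_len(nsub)) {
      frac <- k / nsub
      hk <- list(p_snow = h$p_snow, rain = h$rain, snowmelt = h$snowmelt,
                 q_sf = h$q_sf, q_infil = h$q_infil, q_sz = h$q_sz,
                 q_perc = h$q_perc, q_dz = h$q_dz,
                 v_sf = v_prev$sf + frac * (vs$sf - v_prev$sf),
                 v_sz = v_prev$sz + frac * (vs$sz - v_prev$sz),
                 v_dz = v_prev$dz + frac * (vs$dz - v_prev$dz))
      adv <- step_zone_advection(states, hk, c_rain, cfg$dt)
      states <- adv$states
      for (z in rxn_zones) {
        hz <- switch(z, SF = list(sw = 1, zw = 0, v = hk$v_sf),
                     SZ = list(sw = sw_sz[t], zw = zw_sz[t], v = hk$v_sz),
                     DZ = list(sw = sw_dz[t], zw = zw_dz[t], v = hk$v_dz))
        ctx <- rate_context(h$temp, hz$sw, hz$zw, cfg$dt, hz$v,
                            signed_q10 = cfg$signed_q10)
        res <- integrate_zone_reactions(states[[z]], net$kinetic[[z]], ctx)
        states[[z]] <- res$state
        if (length(res$rates))
          day_rates[names(res$rates)] <- day_rates[names(res$rates)] +
            res$rates / nsub
      }
      # accumulate export mass over substeps (mol/m2/day, averaged below)
      exp_acc <- exp_acc + (h$q_sf * adv$exports$SF + h$q_sz * adv$exports$SZ +
                              h$q_dz * adv$exports$DZ) / nsub
      if (record && k == nsub) {
        rec_zone_tot$SF[t, ] <<- states$SF$totals
        rec_zone_tot$SZ[t, ] <<- states$SZ$totals
        rec_zone_tot$DZ[t, ] <<- states$DZ$totals
        if (length(sec)) {
          rec_zone_sec$SF[t, ] <<- states$SF$speciated$conc[sec]
          rec_zone_sec$SZ[t, ] <<- states$SZ$speciated$conc[sec]
          rec_zone_sec$DZ[t, ] <<- states$DZ$speciated$conc[sec]
        }
        rec_export$SF[t, ] <<- adv$exports$SF
        rec_export$SZ[t, ] <<- adv$exports$SZ
        rec_export$DZ[t, ] <<- adv$exports$DZ
      }
    }
    if (record) {
      rec_rates[t, ] <<- day_rates
      rec_store[t, ] <<- states$snow$conc * states$snow$swe +
        states$SF$totals * states$SF$v_w +
        states$SZ$totals * states$SZ$v_w +
        states$DZ$totals * states$DZ$v_w
      rec_input[t, ] <<- h$precip * c_rain
      rec_outflux[t, ] <<- exp_acc
    }
    states
  }

  if (cfg$spinup_days > 0) {
    for (t in seq_len(min(cfg$spinup_days, n)))
      states <- step_day(states, t, record = FALSE)
    # spin-up refines the initial concentrations only: volumes restart on the
    # day-1 hydrology and the snowpack restarts empty, so the recorded pass
    # sees no storage discontinuity
    states$SF$v_w <- v_sf[1]
    states$SZ$v_w <- v0_sz
    states$DZ$v_w <- v0_dz
    states$snow <- snow_chem_state(0, states$snow$conc)
  }
  for (t in seq_len(n)) states <- step_day(states, t, record = TRUE)

  dates <- hydro$date
  zone_tbl <- function(zone) {
    tot <- rec_zone_tot[[zone]]
    secm <- rec_zone_sec[[zone]]
    d <- as_tibble(tot)
    # aggregates: sum member species (secondaries from speciation; a primary
    # member contributes its free concentration = total minus secondaries)
    for (a in names(aggs)) {
      v <- rep(0, n)
      for (s in aggs[[a]]) {
        if (s %in% colnames(secm)) v <- v + secm[, s]
        else if (s %in% prim) {
          # free primary concentration: total minus secondary contributions
          contrib <- rep(0, n)
          if (length(sec)) {
            tabc <- eqsys$tableau[, s]
            for (ss in sec[tabc[sec] != 0]) contrib <- contrib +
                eqsys$tableau[ss, s] * secm[, ss]
          }
          v <- v + tot[, s] - contrib
        }
      }
      d[[a]] <- v
    }
    for (s in sec) d[[s]] <- secm[, s]
    d$date <- dates; d$zone <- zone
    tidyr::pivot_longer(d, cols = -c("date", "zone"),
                        names_to = "species", values_to = "conc")
  }
  zones_long <- dplyr::bind_rows(zone_tbl("SF"), zone_tbl("SZ"),
                                 zone_tbl("DZ"))

  # stream: flux-weighted mobile totals (and aggregates likewise)
  qt <- hydro$q
  mix <- function(sp_idx) {
    (hydro$q_sf * rec_export$SF[, sp_idx] +
       hydro$q_sz * rec_export$SZ[, sp_idx] +
       hydro$q_dz * rec_export$DZ[, sp_idx]) / ifelse(qt > 0, qt, NA)
  }
  stream <- tibble(date = dates, q = qt)
  for (s in prim[mobp]) stream[[s]] <- mix(s)
  for (a in names(aggs)) {
    za <- zones_long[zones_long$species == a, ]
    wide <- tidyr::pivot_wider(za, names_from = "zone", values_from = "conc")
    stream[[a]] <- (hydro$q_sf * wide$SF + hydro$q_sz * wide$SZ +
                      hydro$q_dz * wide$DZ) / ifelse(qt > 0, qt, NA)
  }

  rates_long <- if (length(all_rids)) {
    as_tibble(rec_rates * 1000) |>
      dplyr::mutate(date = dates) |>
      tidyr::pivot_longer(-"date", names_to = "reaction",
                          values_to = "rate_mmol_m2_day") |>
      dplyr::mutate(zone = zone_of_rid[match(.data$reaction, all_rids)])
  } else {
    tibble(date = numeric(0), reaction = character(0),
           rate_mmol_m2_day = numeric(0), zone = character(0))
  }

  exports_long <- dplyr::bind_rows(lapply(c("SF", "SZ", "DZ"), function(z) {
    qz <- switch(z, SF = hydro$q_sf, SZ = hydro$q_sz, DZ = hydro$q_dz)
    m <- rec_export[[z]] * qz * 1000
    as_tibble(m) |> dplyr::mutate(date = dates, zone = z) |>
      tidyr::pivot_longer(-c("date", "zone"), names_to = "species",
                          values_to = "flux_mmol_m2_day")
  }))

  stores <- as_tibble(rec_store) |> dplyr::mutate(date = dates) |>
    tidyr::pivot_longer(-"date", names_to = "species",
                        values_to = "mass_mol_m2")

  budget <- tibble(
    species = prim,
    input = colSums(rec_input),
    export = colSums(rec_outflux))

  out <- structure(list(stream = stream, zones = zones_long,
                        rates = rates_long, exports = exports_long,
                        stores = stores, budget = budget, hydro = hydro,
                        forcing = forcing, config = cfg,
                        initial_store = rec_store[1, ] -
                          rec_input[1, ] + rec_outflux[1, ]),
                   class = "rt_simoutput")
  out
}

#' @export
print.rt_simoutput <- function(x, ...) {
  cat(sprintf("<rt_simoutput> %d days, %d solutes\n", nrow(x$stream),
              ncol(x$stream) - 2))
  cat("stream concentrations (mol/L):\n")
  print(x$stream, n = 5)
  invisible(x)
}

#' Cumulative solute budget closure of a run
#'
#' For each primary component: cumulative atmospheric input minus cumulative
#' stream export minus the change of all stores (snowpack + three zones),
#' as a fraction of cumulative input. Near 0 for a conservative tracer.
#'
#' @param out An `rt_simoutput`.
#' @return A tibble: `species`, `input`, `export`, `dstore`, `residual`,
#'   `rel_residual`.
#' @export
budget_closure <- function(out) {
  st <- out$stores
  last <- st[st$date == max(st$date), ]
  dstore <- last$mass_mol_m2 - out$initial_store[last$species]
  b <- tibble(species = last$species,
              input = out$budget$input[match(last$species, out$budget$species)],
              export = out$budget$export[match(last$species, out$budget$species)],
              dstore = dstore)
  b$residual <- b$input - b$export - b$dstore
  b$rel_residual <- b$residual / pmax(b$input, 1e-300)
  b
}

#' Write simulation output tables
#'
#' Writes tab-delimited tables (`stream.tsv`, `zones.tsv`, `rates.tsv`,
#' `exports.tsv`, `hydro.tsv`) with documented headers; numeric content
#' round-trips losslessly through [read_sim_tables()].
#'
#' @param out An `rt_simoutput`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
export_tables <- function(out, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stopf("cannot create output directory '%s'", dir)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f), progress = FALSE)
  w(out$stream, "stream.tsv")
  w(out$zones, "zones.tsv")
  w(out$rates, "rates.tsv")
  w(out$exports, "exports.tsv")
  w(out$hydro, "hydro.tsv")
  invisible(dir)
}

#' @rdname export_tables
#' @export
read_sim_tables <- function(dir) {
  r <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                                   progress = FALSE)
  list(stream = r("stream.tsv"), zones = r("zones.tsv"),
       rates = r("rates.tsv"), exports = r("exports.tsv"),
       hydro = r("hydro.tsv"))
}

#' Concentration-discharge summary
#'
#' Least-squares slope of log10 concentration against log10 discharge and the
#' Spearman rank correlation, over days with positive discharge and positive
#' concentration. A positive relationship is a flushing pattern
#' (shallow-enriched solutes), a negative one dilution (deep-enriched
#' solutes). All-constant series get slope 0 and rho 0 with `flag =
#' "constant"`.
#'
#' @param out An `rt_simoutput` (or a data frame with columns `q` and the
#'   solute).
#' @param solute Stream column name (a component or an aggregate).
#' @return A one-row tibble: `solute`, `slope`, `rho`, `n`, `flag`.
#' @export
cq_summary <- function(out, solute) {
  d <- if (inherits(out, "rt_simoutput")) out$stream else out
  if (!solute %in% names(d)) stopf("no stream series for solute '%s'", solute)
  ok <- is.finite(d$q) & d$q > 0 & is.finite(d[[solute]]) & d[[solute]] > 0
  q <- d$q[ok]; c <- d[[solute]][ok]
  if (length(q) < 30)
    stopf("need >= 30 positive-discharge steps for a C-Q summary (have %d)",
          length(q))
  if (stats::sd(c) == 0 || stats::sd(q) == 0)
    return(tibble(solute = solute, slope = 0, rho = 0, n = length(q),
                  flag = "constant"))
  x <- log10(q); y <- log10(c)
  slope <- stats::cov(x, y) / stats::var(x)
  rho <- stats::cor(q, c, method = "spearman")
  tibble(solute = solute, slope = slope, rho = rho, n = length(q),
         flag = "ok")
}
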