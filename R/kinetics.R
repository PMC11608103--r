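#' Temperature dependence factor f(T)
#'
#' Q10-type temperature modifier, `q10 ^ (|temp - 20| / 10)`. With `q10 = 1`
#' the factor is 1 at any temperature. The default follows the absolute-value
#' form (rates rise on both sides of 20 degC); `signed = TRUE` selects the
#' conventional signed exponent `q10 ^ ((temp - 20) / 10)`.
#'
#' @param temp Temperature, degC (vectorized).
#' @param q10 Temperature coefficient (> 0).
#' @param signed Use the signed exponent instead of the absolute value.
#' @return Dimensionless factor, >= 0.
#' @export
env_factor_T <- function(temp, q10, signed = FALSE) {
  stopifnot(q10 > 0)
  expo <- if (signed) (temp - 20) / 10 else abs(temp - 20) / 10
  q10^expo
}

#' Soil moisture dependence factor f(Sw)
#'
#' Piecewise power law peaking at the critical saturation `swc`:
#' `(sw/swc)^n` for `sw <= swc` and `((1-sw)/(1-swc))^n` above it. `n = 0`
#' disables the dependence (factor 1 everywhere). `swc >= 1` keeps the rate on
#' the rising branch over the whole saturation range; `swc = 0` keeps it on
#' the falling branch.
#'
#' @param sw Saturation, fraction in \[0, 1\] (vectorized).
#' @param swc Critical saturation (>= 0).
#' @param n Exponent (0 disables).
#' @return Dimensionless factor in \[0, 1\] (for swc in \[0, 1\]).
#' @export
env_factor_Sw <- function(sw, swc, n) {
  stopifnot(swc >= 0, all(sw >= 0), all(sw <= 1))
  if (n == 0) return(rep(1, length(sw)))
  out <- numeric(length(sw))
  lower <- sw <= swc
  if (swc > 0) out[lower] <- (sw[lower] / swc)^n
  else out[lower] <- 1            # sw = 0 = swc: peak by convention
  out[!lower] <- ((1 - sw[!lower]) / (1 - swc))^n
  out
}

#' Water table depth dependence factor f(Zw)
#'
#' Exponential depth modifier `exp(-alpha_beta * zw)`. Only the product of the
#' magnitude and direction parameters is prescribed; a positive product makes
#' rates rise as the water table rises (shallower `zw`), a negative product
#' the reverse, and 0 disables the dependence.
#'
#' @param zw Water table depth, m (>= 0, vectorized).
#' @param alpha_beta Depth coefficient (1/m).
#' @return Dimensionless factor > 0; equals 1 when `alpha_beta = 0` or `zw = 0`.
#' @export
env_factor_Zw <- function(zw, alpha_beta) {
  stopifnot(all(zw >= 0))
  exp(-alpha_beta * zw)
}

#' Rate evaluation context
#'
#' Environmental conditions under which zone kinetics are evaluated.
#'
#' @param temp Temperature, degC.
#' @param sw Zone saturation, fraction.
#' @param zw Water table depth, m.
#' @param dt Time step, days.
#' @param water_volume Zone water storage, mm (numerically L per m2).
#' @param signed_q10 Use the signed Q10 exponent (see [env_factor_T()]).
#' @return A `rate_context` list.
#' @export
rate_context <- function(temp, sw, zw = 0, dt = 1, water_volume = 1,
                         signed_q10 = FALSE) {
  stopifnot(sw >= 0, sw <= 1, zw >= 0, dt > 0, water_volume > 0)
  structure(list(temp = temp, sw = sw, zw = zw, dt = dt,
                 water_volume = water_volume, signed_q10 = signed_q10),
            class = "rate_context")
}

SECONDS_PER_DAY <- 86400

# concentration seen by Monod/inhibition/catalyst terms: aqueous species from
# the speciated state, solids/pseudo-gases from the prescribed substrate
# availability map
term_conc <- function(sp, state, substrate_conc) {
  if (sp %in% names(state$conc)) return(state$conc[[sp]])
  if (sp %in% names(substrate_conc)) return(substrate_conc[[sp]])
  if (sp %in% names(state$sys$fixed)) return(state$sys$fixed[[sp]])
  stopf("no concentration available for Monod/catalyst species '%s'", sp)
}

#' Kinetic reaction rate with factor breakdown
#'
#' Evaluates `r = k * A * f(T) * f(Sw) * f(Zw) * <law>` where `<law>` is the
#' TST departure-from-equilibrium term `(1 - IAP/Keq)` times optional catalyst
#' activities, or the product of Monod and inhibition terms. The rate constant
#' `k` (mol/m2/s) is converted to per-day; with `A` in m2 per m2 of catchment
#' the rate is in mol per m2 of catchment per day. TST rates are signed:
#' negative when the solution is supersaturated (precipitation).
#'
#' @param rxn An `rt_reaction` (kinetic).
#' @param state An `rt_speciation` for the zone water.
#' @param ctx A [rate_context()].
#' @param A Surface-area term, m2/m2; defaults to the reaction's own
#'   `ssa * substrate_mass`.
#' @param substrate_conc Named availability constants (mol/L equivalent) for
#'   Monod terms on solids/pseudo-gases.
#' @return `kinetic_rate()`: the rate (mol/m2/day). `rate_breakdown()`: a list
#'   with the rate and each factor.
#' @export
kinetic_rate <- function(rxn, state, ctx, A = NULL, substrate_conc = list()) {
  rate_breakdown(rxn, state, ctx, A, substrate_conc)$rate
}

#' @rdname kinetic_rate
#' @export
rate_breakdown <- function(rxn, state, ctx, A = NULL,
                           substrate_conc = list()) {
  if (rxn$kind == "equilibrium")
    stopf("reaction '%s' is an equilibrium reaction, not kinetic", rxn$id)
  if (is.null(A)) A <- reaction_area(rxn)
  f_t <- env_factor_T(ctx$temp, rxn$q10, signed = isTRUE(ctx$signed_q10))
  f_sw <- env_factor_Sw(ctx$sw, rxn$swc, rxn$n)
  f_zw <- env_factor_Zw(ctx$zw, rxn$alpha_beta)
  k_day <- 10^rxn$log10_k * SECONDS_PER_DAY
  base <- k_day * A * f_t * f_sw * f_zw
  saturation <- NA_real_; monod <- NA_real_; inhibition <- NA_real_
  if (rxn$kind == "kinetic-tst") {
    if (is.null(rxn$log10_keq)) stopf("TST reaction '%s' lacks Keq", rxn$id)
    liap <- log_ion_activity_product(state, rxn)
    saturation <- 1 - 10^(liap - rxn$log10_keq)
    cat_term <- 1
    for (sp in names(rxn$catalyst))
      cat_term <- cat_term * term_conc(sp, state, substrate_conc)^rxn$catalyst[[sp]]
    rate <- base * saturation * cat_term
  } else {
    monod <- 1
    for (sp in names(rxn$monod)) {
      cc <- term_conc(sp, state, substrate_conc)
      monod <- monod * cc / (cc + rxn$monod[[sp]])
    }
    inhibition <- 1
    for (sp in names(rxn$inhibition)) {
      cc <- term_conc(sp, state, substrate_conc)
      inhibition <- inhibition * rxn$inhibition[[sp]] / (cc + rxn$inhibition[[sp]])
    }
    rate <- base * monod * inhibition
  }
  list(rate = rate, f_t = f_t, f_sw = f_sw, f_zw = f_zw,
       saturation = saturation, monod = monod, inhibition = inhibition)
}

#' Zone chemistry state
#'
#' Component totals and speciated concentrations of one well-mixed zone.
#'
#' @param zone Zone label (`"SF"`, `"SZ"`, `"DZ"`).
#' @param v_w Water storage, mm.
#' @param totals Named component totals, mol/L.
#' @param eqsys An `rt_eqsys` (optional; without it the state is
#'   transport-only and totals are reported as concentrations).
#' @param substrate_conc Named substrate availability constants, mol/L.
#' @return An object of class `rt_zone_chem`.
#' @export
zone_chem_state <- function(zone, v_w, totals, eqsys = NULL,
                            substrate_conc = list()) {
  st <- structure(list(zone = zone, v_w = v_w, totals = totals,
                       eqsys = eqsys, substrate_conc = substrate_conc,
                       speciated = NULL), class = "rt_zone_chem")
  if (!is.null(eqsys)) st$speciated <- speciate(totals, eqsys)
  st
}

# rate vector (per reaction) and totals derivative (mol/L/day) at given totals
zone_rates <- function(totals, rxns, ctx, eqsys, substrate_conc, warm = NULL) {
  state <- speciate(totals, eqsys, init = warm)
  rates <- vapply(rxns, function(r)
    kinetic_rate(r, state, ctx, substrate_conc = substrate_conc), numeric(1))
  dtot <- stats::setNames(numeric(length(eqsys$primaries)), eqsys$primaries)
  for (i in seq_along(rxns)) {
    st <- rxns[[i]]$stoich
    sp <- intersect(names(st), eqsys$primaries)
    dtot[sp] <- dtot[sp] + st[sp] * rates[i]
  }
  list(rates = rates, dtot = dtot / ctx$water_volume, state = state)
}

#' Integrate kinetic reactions within a zone over one step
#'
#' Advances the zone's component totals over `ctx$dt` using a Crank-Nicolson
#' (trapezoidal) step solved by Newton-Raphson on the end-of-step totals;
#' on convergence failure the step is halved repeatedly (up to `max_halvings`).
#' The state is re-speciated and the returned per-reaction rates are
#' time-averaged over the full step, so that for every primary component
#' `delta(total) = sum(stoich * mean rate) * dt / water_volume` holds exactly.
#'
#' @param state An `rt_zone_chem` (speciated).
#' @param rxns List of kinetic `rt_reaction`s.
#' @param ctx A [rate_context()]; `ctx$water_volume` converts area-normalized
#'   rates (mol/m2/day) to concentration change (mol/L/day).
#' @param max_halvings Maximum number of step halvings (default 12).
#' @return A list: `state` (updated `rt_zone_chem`) and `rates` (named
#'   time-averaged rates, mol/m2/day).
#' @export
integrate_zone_reactions <- function(state, rxns, ctx, max_halvings = 12) {
  stopifnot(inherits(state, "rt_zone_chem"))
  prim <- state$eqsys$primaries
  rids <- vapply(rxns, `[[`, "", "id")
  mean_rates <- stats::setNames(numeric(length(rxns)), rids)
  if (!length(rxns)) {
    return(list(state = state, rates = mean_rates))
  }
  totals <- expand_named(state$totals, prim)
  sc <- state$substrate_conc
  warm <- state$speciated$log10_prim

  cn_step <- function(T0, h, warm) {
    # Crank-Nicolson: T1 = T0 + h/2 (f(T0) + f(T1)); chord Newton on T1
    ctx_h <- ctx; ctx_h$dt <- h
    r0 <- zone_rates(T0, rxns, ctx_h, state$eqsys, sc, warm)
    T1 <- T0 + h * r0$dtot            # explicit predictor
    if (any_invalid(T1, state$eqsys)) T1 <- pmax(T0 + h * r0$dtot, T0 * 0.5)
    J <- NULL
    for (it in 1:25) {
      r1 <- tryCatch(zone_rates(T1, rxns, ctx_h, state$eqsys, sc, warm),
                     error = function(e) NULL)
      if (is.null(r1)) return(NULL)
      G <- T1 - T0 - h / 2 * (r0$dtot + r1$dtot)
      scale <- pmax(abs(T0), abs(T1), 1e-15)
      if (max(abs(G) / scale) < 1e-11) {
        T1[T1 < 0 & T1 > -1e-18] <- 0   # roundoff-negative totals
        if (any_invalid(T1, state$eqsys)) return(NULL)
        return(list(T1 = T1, mean = (r0$rates + r1$rates) / 2,
                    dmean = (r0$dtot + r1$dtot) / 2, warm = r1$state$log10_prim))
      }
      if (is.null(J)) {
        # finite-difference Jacobian of f at T1, reused across iterations
        n <- length(T1)
        Jf <- matrix(0, n, n)
        for (j in seq_len(n)) {
          Tp <- T1
          eps <- max(abs(Tp[j]) * 1e-6, 1e-14)
          Tp[j] <- Tp[j] + eps
          rp <- tryCatch(zone_rates(Tp, rxns, ctx_h, state$eqsys, sc, warm),
                         error = function(e) NULL)
          if (is.null(rp)) return(NULL)
          Jf[, j] <- (rp$dtot - r1$dtot) / eps
        }
        J <- diag(n) - h / 2 * Jf
      }
      dT <- tryCatch(solve(J, -G), error = function(e) NULL)
      if (is.null(dT) || any(!is.finite(dT))) return(NULL)
      T1 <- T1 + dT
    }
    NULL
  }

  advance <- function(T0, h, depth, warm) {
    res <- cn_step(T0, h, warm)
    if (!is.null(res)) {
      mean_rates <<- mean_rates + res$mean * h / ctx$dt
      return(list(T1 = res$T1, warm = res$warm))
    }
    if (depth >= max_halvings)
      stopf("reaction integration failed to converge in zone %s at minimum substep (dt = %g d)",
            state$zone, h)
    a <- advance(T0, h / 2, depth + 1, warm)
    advance(a$T1, h / 2, depth + 1, a$warm)
  }

  out <- advance(totals, ctx$dt, 0, warm)
  state$totals <- out$T1
  state$speciated <- speciate(out$T1, state$eqsys, init = out$warm)
  list(state = state, rates = mean_rates)
}

# end-of-step totals that speciation cannot represent (negative totals for
# all-positive components) invalidate a step
any_invalid <- function(totals, eqsys) {
  tab <- eqsys$tableau
  allpos <- if (length(eqsys$secondaries))
    apply(tab >= 0, 2, all) else rep(TRUE, length(eqsys$primaries))
  any(totals[allpos] < 0)
}
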