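#' Equilibrium system (tableau) of a reaction network
#'
#' Expresses every secondary (and sorbed) species as a linear combination of
#' primary species in log-activity space by resolving its defining equilibrium
#' reaction, substituting through intermediate secondaries where necessary.
#' Fixed-activity species (water, solids at activity 1, pseudo-gases at their
#' prescribed activity) are folded into the constant term. Fails if any
#' secondary cannot be expressed in terms of primaries.
#'
#' @param net An `rt_network`.
#' @return An object of class `rt_eqsys` with fields `primaries`, `secondaries`,
#'   `tableau` (matrix, secondaries x primaries), `logk` (constants such that
#'   `log10 a_sec = logk + tableau %*% log10 a_prim`), `fixed` (named fixed
#'   activities) and `equilibrium` (the defining reactions).
#' @export
equilibrium_system <- function(net) {
  stopifnot(inherits(net, "rt_network"))
  prim <- net$primaries
  secs <- net$secondaries
  fixed <- net$fixed
  tab <- matrix(0, length(secs), length(prim),
                dimnames = list(secs, prim))
  logk <- stats::setNames(rep(NA_real_, length(secs)), secs)
  resolved <- stats::setNames(rep(FALSE, length(secs)), secs)
  repeat {
    progressed <- FALSE
    for (s in secs[!resolved]) {
      rxn <- net$equilibrium[[s]]
      nu <- rxn$stoich
      others <- setdiff(names(nu), s)
      dep_sec <- intersect(others, secs)
      if (length(dep_sec) && !all(resolved[dep_sec])) next
      unknown <- setdiff(others, c(prim, names(fixed), secs))
      if (length(unknown))
        stopf("defining reaction of '%s' references undeclared species: %s",
              s, paste(unknown, collapse = ", "))
      nus <- nu[[s]]
      const <- rxn$log10_keq
      coefs <- stats::setNames(rep(0, length(prim)), prim)
      for (sp in others) {
        if (sp %in% names(fixed)) {
          const <- const - nu[[sp]] * log10(fixed[[sp]])
        } else if (sp %in% prim) {
          coefs[sp] <- coefs[sp] - nu[[sp]]
        } else { # resolved secondary: substitute its expansion
          const <- const - nu[[sp]] * logk[[sp]]
          coefs <- coefs - nu[[sp]] * tab[sp, ]
        }
      }
      logk[s] <- const / nus
      tab[s, ] <- coefs / nus
      resolved[s] <- TRUE
      progressed <- TRUE
    }
    if (all(resolved)) break
    if (!progressed)
      stopf("secondary species cannot be resolved from primaries: %s",
            paste(secs[!resolved], collapse = ", "))
  }
  structure(list(primaries = prim, secondaries = secs, tableau = tab,
                 logk = logk, fixed = fixed, equilibrium = net$equilibrium,
                 species = net$species),
            class = "rt_eqsys")
}

#' Equilibrium speciation of component totals
#'
#' Solves the coupled mass-action and component mole-balance equations for all
#' species concentrations, given the total (component) concentrations of the
#' primary species. Unknowns are log10 concentrations of the primaries;
#' the damped Newton-Raphson iteration (step cap 1 log10 unit per component
#' per iteration) runs to a relative mole-balance tolerance of `rtol`.
#' Activities equal concentrations (dilute-solution convention).
#'
#' @param totals Named numeric of component totals (mol/L) for every primary
#'   species. Totals of components with negative-coefficient species (e.g. the
#'   proton balance with OH-) may be negative.
#' @param sys An `rt_eqsys` (or an `rt_network`, from which the system is
#'   taken).
#' @param init Optional warm start: named log10 primary concentrations.
#' @param maxit,rtol Iteration cap and relative tolerance.
#' @return An object of class `rt_speciation`: `conc` (all species, mol/L),
#'   `totals`, `log_iap` (per equilibrium reaction), `iterations`, `residual`.
#' @export
speciate <- function(totals, sys, init = NULL, maxit = 100, rtol = 1e-10) {
  if (inherits(sys, "rt_network")) sys <- sys$eqsys
  stopifnot(inherits(sys, "rt_eqsys"))
  prim <- sys$primaries
  if (!all(prim %in% names(totals)))
    stopf("totals missing for primary species: %s",
          paste(setdiff(prim, names(totals)), collapse = ", "))
  Tt <- as.numeric(totals[prim]); names(Tt) <- prim
  if (any(!is.finite(Tt))) stopf("non-finite component totals")
  tab <- sys$tableau
  nsec <- length(sys$secondaries)

  # components whose species all enter positively must have positive totals;
  # exactly-zero totals (e.g. no sorption sites) drop out of the solve
  allpos <- if (nsec) apply(tab >= 0, 2, all) else rep(TRUE, length(prim))
  zero <- Tt == 0 & allpos
  if (any(Tt < 0 & allpos))
    stopf("negative total for component(s) %s whose species are all positive",
          paste(prim[Tt < 0 & allpos], collapse = ", "))
  act <- !zero
  # secondaries involving a zeroed component with positive coefficient are zero
  sec_zero <- if (nsec) apply(tab[, zero, drop = FALSE] > 0, 1, any) else logical(0)
  if (nsec && any(apply(tab[, zero, drop = FALSE] < 0, 1, any)))
    stopf("secondary species with negative dependence on an absent component")

  tab_a <- tab[!sec_zero, act, drop = FALSE]
  logk_a <- sys$logk[!sec_zero]
  Ta <- Tt[act]
  npa <- sum(act)

  if (npa == 0) {
    # every component absent: the all-zero state is exact
    conc <- stats::setNames(rep(0, length(prim) + nsec),
                            c(prim, sys$secondaries))
    state <- structure(list(conc = conc, totals = Tt, sys = sys,
                            iterations = 0L, residual = 0,
                            log10_prim = stats::setNames(numeric(0),
                                                         character(0))),
                       class = "rt_speciation")
    state$log_iap <- vapply(sys$equilibrium, function(rxn)
      log_ion_activity_product(state, rxn), numeric(1))
    return(state)
  }

  solve_from <- function(x) {
    ln10 <- log(10)
    for (it in seq_len(maxit)) {
      cp <- 10^x
      cs <- if (nrow(tab_a)) as.numeric(10^(logk_a + tab_a %*% x)) else numeric(0)
      contrib <- if (nrow(tab_a)) as.numeric(crossprod(tab_a, cs)) else 0
      FF <- cp + contrib - Ta
      abs_tot <- cp + (if (nrow(tab_a)) as.numeric(crossprod(abs(tab_a), cs)) else 0)
      scale <- pmax(abs(Ta), abs_tot, 1e-300)
      if (all(abs(FF) <= rtol * scale))
        return(list(x = x, it = it, res = max(abs(FF) / scale)))
      J <- diag(cp, npa, npa)
      if (nrow(tab_a)) J <- J + crossprod(tab_a, cs * tab_a)
      J <- ln10 * J
      dx <- tryCatch(solve(J, -FF), error = function(e) NULL)
      if (is.null(dx) || any(!is.finite(dx))) return(NULL)
      dx <- pmin(pmax(dx, -1), 1)       # damping: max 1 log10 unit per step
      x <- pmin(pmax(x + dx, -30), 3)
      if (any(!is.finite(x))) return(NULL)
    }
    NULL
  }

  starts <- list()
  if (!is.null(init) && all(prim[act] %in% names(init)))
    starts <- c(starts, list(as.numeric(init[prim[act]])))
  base <- log10(pmax(abs(Ta), 1e-12))
  starts <- c(starts, list(base, base - 3, base + 1, rep(-7, npa), rep(-4, npa)))
  sol <- NULL
  for (s in starts) {
    sol <- solve_from(s)
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stopf("speciation failed to converge (totals: %s)",
          paste(sprintf("%s=%.3g", prim, Tt), collapse = ", "))

  conc <- stats::setNames(rep(0, length(prim) + nsec),
                          c(prim, sys$secondaries))
  conc[prim[act]] <- 10^sol$x
  if (nrow(tab_a))
    conc[rownames(tab_a)] <- as.numeric(10^(logk_a + tab_a %*% sol$x))

  state <- structure(list(conc = conc, totals = Tt, sys = sys,
                          iterations = sol$it, residual = sol$res,
                          log10_prim = stats::setNames(sol$x, prim[act])),
                     class = "rt_speciation")
  state$log_iap <- vapply(sys$equilibrium, function(rxn)
    log_ion_activity_product(state, rxn), numeric(1))
  state
}

#' Recompute component totals from a speciated state
#'
#' @param state An `rt_speciation`.
#' @return Named numeric of totals (mol/L) over the primary species.
#' @export
component_totals <- function(state) {
  sys <- state$sys
  tot <- state$conc[sys$primaries]
  if (length(sys$secondaries))
    tot <- tot + as.numeric(crossprod(sys$tableau,
                                      state$conc[sys$secondaries]))
  tot
}

#' log10 ion activity product of a reaction
#'
#' `sum(stoich * log10 activity)` over participating species, with products
#' positive and reactants negative; solids and pseudo-gases contribute their
#' fixed activities.
#'
#' @param state An `rt_speciation`.
#' @param rxn An `rt_reaction`.
#' @return log10 IAP (dimensionless).
#' @export
log_ion_activity_product <- function(state, rxn) {
  fixed <- state$sys$fixed
  acts <- vapply(names(rxn$stoich), function(sp) {
    if (sp %in% names(state$conc)) state$conc[[sp]]
    else if (sp %in% names(fixed)) fixed[[sp]]
    else stopf("species '%s' absent from speciation state", sp)
  }, numeric(1))
  if (any(acts <= 0)) return(-Inf)
  sum(rxn$stoich * log10(acts))
}

#' Tidy a speciation state
#'
#' @param x An `rt_speciation`.
#' @param ... Unused.
#' @return A tibble with one row per species: concentration and phase.
#' @export
tidy.rt_speciation <- function(x, ...) {
  ph <- x$sys$species
  tibble(species = names(x$conc),
         conc = as.numeric(x$conc),
         phase = ph$phase[match(names(x$conc), ph$name)])
}

#' @export
print.rt_speciation <- function(x, ...) {
  cat(sprintf("<rt_speciation> converged in %d iterations (residual %.2e)\n",
              x$iterations, x$residual))
  print(tidy(x), n = Inf)
  invisible(x)
}
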