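#' Parse a reaction signature string
#'
#' Reaction signatures are written `"reactants <op> products"` where `<op>` is
#' `=` or `<->` (reversible) or `->` (irreversible), each side is a
#' `+`-separated list of terms, and each term is an optional numeric
#' stoichiometric coefficient followed by a species name
#' (e.g. `"Carbonate_SZ(s) -> 1.1 Ca++ + 0.5 HCO3-"`). Species names carry no
#' spaces; the term separator is a `+` surrounded by spaces, so charge signs in
#' names like `Ca++` are unambiguous.
#'
#' @param text Reaction signature string.
#' @return A list with `stoich` (named numeric; reactants negative, products
#'   positive) and `reversible` (logical).
#' @examples
#' parse_reaction("CO2(aq) + H2O = HCO3- + H+")$stoich
#' @export
parse_reaction <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- trimws(text)
  if (txt == "") stopf("empty reaction signature")
  op <- if (grepl("<->", txt, fixed = TRUE)) "<->"
        else if (grepl("->", txt, fixed = TRUE)) "->"
        else if (grepl("=", txt, fixed = TRUE)) "="
        else stopf("reaction '%s' has no '=', '<->' or '->' separator", txt)
  sides <- strsplit(txt, op, fixed = TRUE)[[1]]
  if (length(sides) != 2) stopf("reaction '%s' is not two-sided", txt)
  accumulate <- function(side, sign) {
    side <- trimws(side)
    out <- stats::setNames(numeric(0), character(0))
    if (side == "") return(out)
    for (term in strsplit(side, " + ", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1) { coef <- 1; name <- parts[1] }
      else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stopf("bad coefficient '%s' in reaction '%s'",
                               parts[1], txt)
        name <- parts[2]
      } else stopf("cannot parse term '%s' in reaction '%s'", term, txt)
      out[name] <- (if (name %in% names(out)) out[[name]] else 0) + sign * coef
    }
    out
  }
  lhs <- accumulate(sides[1], -1)
  rhs <- accumulate(sides[2], +1)
  stoich <- lhs
  for (nm in names(rhs))
    stoich[nm] <- (if (nm %in% names(stoich)) stoich[[nm]] else 0) + rhs[[nm]]
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) stopf("reaction '%s' has empty net stoichiometry", txt)
  list(stoich = stoich, reversible = op != "->")
}

#' Canonical reaction signature
#'
#' Renders a stoichiometry map back to the canonical signature string used as
#' database key: reactants and products each sorted alphabetically, reversible
#' reactions joined by `=`, irreversible by `->`.
#'
#' @param stoich Named numeric stoichiometry (reactants negative).
#' @param reversible Logical.
#' @return A single string.
#' @export
reaction_signature <- function(stoich, reversible = TRUE) {
  lhs <- stoich[stoich < 0]; rhs <- stoich[stoich > 0]
  side <- function(s) {
    s <- s[order(names(s), method = "radix")]
    terms <- vapply(seq_along(s), function(i) {
      coef <- abs(s[[i]])
      if (coef == 1) names(s)[i] else paste(fmt_num(coef), names(s)[i])
    }, character(1))
    paste(terms, collapse = " + ")
  }
  paste(side(lhs), if (reversible) "=" else "->", side(rhs))
}

#' Define a reaction
#'
#' Constructs a validated reaction definition: an equilibrium reaction, a
#' transition-state-theory (TST) kinetic reaction, or a Monod-type kinetic
#' reaction, together with its rate parameters and environmental-dependence
#' parameters (Q10 temperature factor, soil-moisture exponent/critical
#' saturation, water-table coefficient).
#'
#' @param id Reaction identifier.
#' @param kind One of `"equilibrium"`, `"kinetic-tst"`, `"kinetic-monod"`.
#' @param reaction Reaction signature string (see [parse_reaction()]).
#' @param log10_keq log10 equilibrium constant (required for equilibrium and
#'   TST reactions).
#' @param log10_k log10 rate constant, mol/m2/s (kinetic reactions).
#' @param ssa Specific surface area of the reacting material, m2/g.
#' @param substrate Name of the solid / pseudo-gas species whose abundance the
#'   rate scales on (optional bookkeeping label).
#' @param substrate_mass Reactive substrate mass, g per m2 of catchment; the
#'   constant surface-area term is `A = ssa * substrate_mass` (m2/m2).
#' @param monod Named numeric of half-saturation constants KM (mol/L) keyed by
#'   species.
#' @param inhibition Named numeric of inhibition constants KI (mol/L).
#' @param catalyst Named numeric of catalyst activity exponents m.
#' @param q10 Temperature coefficient Q10 (> 0).
#' @param n Soil-moisture dependence exponent (0 disables).
#' @param swc Critical saturation at which the moisture factor peaks.
#' @param alpha_beta Water-table depth coefficient (product alpha*beta, 1/m).
#' @return An object of class `rt_reaction`.
#' @export
rt_reaction <- function(id, kind, reaction,
                        log10_keq = NULL, log10_k = NULL, ssa = NULL,
                        substrate = NULL, substrate_mass = NULL,
                        monod = NULL, inhibition = NULL, catalyst = NULL,
                        q10 = 1, n = 0, swc = 1, alpha_beta = 0) {
  kind <- match.arg(kind, c("equilibrium", "kinetic-tst", "kinetic-monod"))
  parsed <- parse_reaction(reaction)
  if (kind == "equilibrium") {
    if (is.null(log10_keq)) stopf("equilibrium reaction '%s' needs log10_keq", id)
    if (!is.null(log10_k) || !is.null(substrate_mass))
      stopf("equilibrium reaction '%s' must not carry kinetic parameters", id)
  } else {
    if (is.null(log10_k)) stopf("kinetic reaction '%s' needs log10_k", id)
    if (kind == "kinetic-tst" && is.null(log10_keq))
      stopf("TST reaction '%s' needs log10_keq", id)
  }
  if (!is.null(monod) && any(unlist(monod) <= 0))
    stopf("reaction '%s': Monod KM must be > 0", id)
  if (!is.null(inhibition) && any(unlist(inhibition) <= 0))
    stopf("reaction '%s': inhibition KI must be > 0", id)
  if (q10 <= 0) stopf("reaction '%s': q10 must be > 0", id)
  if (swc < 0) stopf("reaction '%s': swc must be >= 0", id)
  structure(list(
    id = id, kind = kind,
    stoich = parsed$stoich, reversible = parsed$reversible,
    log10_keq = log10_keq, log10_k = log10_k, ssa = ssa,
    substrate = substrate, substrate_mass = substrate_mass,
    monod = unlist(monod), inhibition = unlist(inhibition),
    catalyst = unlist(catalyst),
    q10 = q10, n = n, swc = swc, alpha_beta = alpha_beta
  ), class = "rt_reaction")
}

#' @export
print.rt_reaction <- function(x, ...) {
  cat(sprintf("<rt_reaction> %s [%s]\n  %s\n", x$id, x$kind,
              reaction_signature(x$stoich, x$reversible)))
  if (!is.null(x$log10_keq)) cat(sprintf("  log10 Keq = %g\n", x$log10_keq))
  if (!is.null(x$log10_k))
    cat(sprintf("  log10 k = %g mol/m2/s, A = %g m2/m2\n", x$log10_k,
                reaction_area(x)))
  invisible(x)
}

# Constant surface-area term A (m2 per m2 catchment); 1 when no SSA/mass given
# (rate then reads mol/m2/day per unit area term).
reaction_area <- function(rxn) {
  if (is.null(rxn$ssa) || is.null(rxn$substrate_mass)) return(1)
  rxn$ssa * rxn$substrate_mass
}

#' Stoichiometric increment of a reaction
#'
#' Species amounts added by advancing a reaction by a given extent:
#' `increment = stoichiometry * extent` with reactant entries negative and
#' product entries positive.
#'
#' @param reaction An [rt_reaction()].
#' @param extent Reaction extent (mol/m2).
#' @return Named numeric of per-species increments (mol/m2).
#' @examples
#' r <- rt_reaction("diss", "kinetic-tst", "M(s) -> 1.1 Ca++ + 0.5 HCO3-",
#'                  log10_keq = -7.4, log10_k = -9.19)
#' stoichiometric_increment(r, 1)
#' @export
stoichiometric_increment <- function(reaction, extent) {
  stopifnot(inherits(reaction, "rt_reaction"), is.finite(extent))
  reaction$stoich * extent
}
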