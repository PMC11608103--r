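#' Build a validated reaction network
#'
#' Assembles species declarations, equilibrium (secondary-species-defining)
#' reactions and per-zone kinetic reactions into a validated network. Missing
#' equilibrium/kinetic constants are resolved from the geochemical database by
#' reaction signature; values given in the configuration override the database.
#'
#' The configuration is a YAML document (text or parsed list) with the schema
#' documented in the README: a `species` block declaring `primary`,
#' `sorption_site`, `solid`, `pseudo_gas`, `secondary` and `sorbed` species
#' (secondary/sorbed species map name to defining reaction signature), an
#' optional `aggregates` block (reported sums such as DIC), per-zone `kinetic`
#' reaction lists, and optional per-zone `substrate_conc` constants (mol/L
#' equivalents for Monod terms on solids/pseudo-gases).
#'
#' @param config Network configuration: YAML text, a file path, or a parsed
#'   list.
#' @param db An `rt_database` (default [default_database()]).
#' @return An object of class `rt_network`.
#' @export
build_network <- function(config, db = default_database()) {
  cfg <- as_config_list(config)
  sp <- cfg$species %||% stopf("network config lacks a 'species' block")
  primaries <- c(unlist(sp$primary), unlist(sp$sorption_site))
  if (!length(primaries)) stopf("network config declares no primary species")
  phase <- c(
    stats::setNames(rep("aqueous-primary", length(sp$primary)),
                    unlist(sp$primary)),
    stats::setNames(rep("sorption-site", length(sp$sorption_site)),
                    unlist(sp$sorption_site)))

  # fixed-activity species: solids (activity 1), pseudo-gases (prescribed),
  # and water
  fixed <- c("H2O" = 1)
  for (s in unlist(sp$solid)) fixed[s] <- 1
  if (!is.null(sp$pseudo_gas))
    for (s in names(sp$pseudo_gas)) fixed[s] <- as.numeric(sp$pseudo_gas[[s]])
  phase <- c(phase,
             stats::setNames(rep("solid", length(sp$solid)), unlist(sp$solid)),
             stats::setNames(rep("pseudo-gas", length(sp$pseudo_gas)),
                             names(sp$pseudo_gas)))

  # secondary species: defining equilibrium reactions
  sec_defs <- c(sp$secondary, sp$sorbed)
  sec_phase <- c(rep("aqueous-secondary", length(sp$secondary)),
                 rep("sorbed", length(sp$sorbed)))
  names(sec_phase) <- c(names(sp$secondary), names(sp$sorbed))
  secondaries <- names(sec_defs)
  phase <- c(phase, sec_phase)
  if (anyDuplicated(names(phase)))
    stopf("duplicate species name(s): %s",
          paste(unique(names(phase)[duplicated(names(phase))]), collapse = ", "))

  equilibrium <- list()
  for (s in secondaries) {
    def <- sec_defs[[s]]
    if (is.character(def)) def <- list(reaction = def)
    entry <- db_lookup(db, def$reaction)
    keq <- def$log10_keq %||% entry$log10_keq
    if (is.null(keq))
      stopf("secondary species '%s': reaction '%s' not in database and no log10_keq given",
            s, def$reaction)
    equilibrium[[s]] <- rt_reaction(
      id = paste0("eq_", s), kind = "equilibrium",
      reaction = def$reaction, log10_keq = keq)
    if (!s %in% names(equilibrium[[s]]$stoich))
      stopf("secondary species '%s' does not appear in its defining reaction '%s'",
            s, def$reaction)
  }

  known <- c(primaries, names(fixed), secondaries)

  # per-zone kinetic reactions
  kinetic <- list(SF = list(), SZ = list(), DZ = list())
  for (zone in intersect(names(cfg$zones %||% list()), names(kinetic))) {
    for (k in cfg$zones[[zone]]$kinetic %||% list()) {
      entry <- db_lookup(db, k$reaction)
      kind <- switch(k$kind %||% "tst",
                     tst = "kinetic-tst", monod = "kinetic-monod",
                     stopf("reaction '%s': unknown kind '%s'", k$id, k$kind))
      rxn <- rt_reaction(
        id = k$id %||% stopf("kinetic reaction in zone %s lacks an id", zone),
        kind = kind, reaction = k$reaction,
        log10_keq = k$log10_keq %||% entry$log10_keq,
        log10_k = k$log10_k %||% entry$log10_k,
        ssa = k$ssa %||% entry$ssa,
        substrate = k$substrate, substrate_mass = k$substrate_mass,
        monod = k$monod, inhibition = k$inhibition, catalyst = k$catalyst,
        q10 = k$q10 %||% 1, n = k$n %||% 0, swc = k$swc %||% 1,
        alpha_beta = k$alpha_beta %||% 0)
      bad <- setdiff(names(rxn$stoich), known)
      if (length(bad))
        stopf("kinetic reaction '%s' references undeclared species: %s",
              rxn$id, paste(bad, collapse = ", "))
      bad <- setdiff(names(rxn$monod), c(known))
      if (length(bad))
        stopf("kinetic reaction '%s' Monod term on undeclared species: %s",
              rxn$id, paste(bad, collapse = ", "))
      kinetic[[zone]] <- c(kinetic[[zone]], list(rxn))
    }
  }

  # aggregate (reporting) sums
  aggregates <- lapply(cfg$aggregates %||% list(), unlist)
  for (a in names(aggregates)) {
    bad <- setdiff(aggregates[[a]], known)
    if (length(bad))
      stopf("aggregate '%s' references undeclared species: %s", a,
            paste(bad, collapse = ", "))
  }

  sp_names <- names(phase)
  sp_phase <- unname(phase)
  species <- tibble(
    name = sp_names, phase = sp_phase,
    mobile = sp_phase %in% c("aqueous-primary", "aqueous-secondary"),
    activity = unname(fixed[sp_names]))

  net <- structure(list(
    species = species, primaries = primaries, secondaries = secondaries,
    fixed = fixed, equilibrium = equilibrium, kinetic = kinetic,
    aggregates = aggregates,
    substrate_conc = lapply(cfg$substrate_conc %||% list(), unlist),
    config = cfg), class = "rt_network")
  # validation: every secondary must be resolvable in terms of primaries
  net$eqsys <- equilibrium_system(net)
  net
}

as_config_list <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config))
  if (length(config) == 1 && !grepl("\n", config) && file.exists(config))
    return(yaml::read_yaml(config))
  yaml::yaml.load(paste(config, collapse = "\n"))
}

#' @export
print.rt_network <- function(x, ...) {
  cat(sprintf("<rt_network> %d primary, %d secondary species\n",
              length(x$primaries), length(x$secondaries)))
  cat("  primaries:", paste(x$primaries, collapse = ", "), "\n")
  if (length(x$secondaries))
    cat("  secondaries:", paste(x$secondaries, collapse = ", "), "\n")
  for (z in names(x$kinetic))
    if (length(x$kinetic[[z]]))
      cat(sprintf("  %s kinetics: %s\n", z,
                  paste(vapply(x$kinetic[[z]], `[[`, "", "id"),
                        collapse = ", ")))
  invisible(x)
}

#' Tidy a reaction network
#'
#' One row per reaction (equilibrium and kinetic), with its zone, kind, rate
#' parameters and environmental-dependence parameters.
#'
#' @param x An `rt_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rt_network <- function(x, ...) {
  row <- function(rxn, zone) {
    tibble(id = rxn$id, zone = zone, kind = rxn$kind,
           reaction = reaction_signature(rxn$stoich, rxn$reversible),
           log10_keq = rxn$log10_keq %||% NA_real_,
           log10_k = rxn$log10_k %||% NA_real_,
           ssa = rxn$ssa %||% NA_real_,
           area = if (rxn$kind == "equilibrium") NA_real_ else reaction_area(rxn),
           q10 = if (rxn$kind == "equilibrium") NA_real_ else rxn$q10,
           n = if (rxn$kind == "equilibrium") NA_real_ else rxn$n,
           swc = if (rxn$kind == "equilibrium") NA_real_ else rxn$swc,
           alpha_beta = if (rxn$kind == "equilibrium") NA_real_ else rxn$alpha_beta)
  }
  rows <- c(lapply(x$equilibrium, row, zone = "all"),
            unlist(lapply(names(x$kinetic), function(z)
              lapply(x$kinetic[[z]], row, zone = z)), recursive = FALSE))
  dplyr::bind_rows(rows)
}

#' Serialize a network configuration
#'
#' Writes the YAML configuration a network was built from;
#' `build_network(serialize_network(net), db)` reproduces the network.
#'
#' @param net An `rt_network`.
#' @return YAML text.
#' @export
serialize_network <- function(net) {
  stopifnot(inherits(net, "rt_network"))
  yaml::as.yaml(net$config)
}
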