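#' Read a simulation configuration file
#'
#' Reads the YAML simulation-configuration dialect (schema in the README):
#' `forcing` (synthetic recipe or file), `hbv` (parameter map or HBV-light
#' file paths), `zones`, `network` and `database` (paths, relative to the
#' config file), `precip_chem`, `initial`, `dt`, `spinup_days`, `seed` and
#' `options`. Overlay lists can disable named reactions
#' (`disable_reactions`), expressing multi-case runs as config variants.
#'
#' @param path Config file path.
#' @param overlay Optional named list merged over the file contents (one level
#'   deep), e.g. `list(disable_reactions = "Denitrification_DZ")`.
#' @return An [sim_config()].
#' @export
read_sim_config <- function(path, overlay = list()) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  for (k in names(overlay)) cfg[[k]] <- overlay[[k]]
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)

  db <- if (is.null(cfg$database)) default_database()
        else parse_database(readLines(rel(cfg$database), warn = FALSE))
  net <- build_network(rel(cfg$network %||%
                             stopf("config lacks a 'network' entry")), db)
  if (length(cfg$disable_reactions))
    net <- disable_reactions(net, unlist(cfg$disable_reactions))

  forcing <- if (!is.null(cfg$forcing$file)) {
    list(file = rel(cfg$forcing$file))
  } else {
    spec_args <- cfg$forcing$spec %||% list()
    if (!is.null(spec_args$chem)) spec_args$chem <- unlist(spec_args$chem)
    list(source = "synthetic", spec = do.call(climate_spec, spec_args),
         years = cfg$forcing$years %||% 2)
  }
  hbv <- if (!is.null(cfg$hbv$results))
    list(results = rel(cfg$hbv$results), params = rel(cfg$hbv$params))
  else do.call(hbv_params, cfg$hbv %||% list())

  sim_config(
    network = net, forcing = forcing, hbv = hbv,
    zones = do.call(zone_config, cfg$zones %||% list()),
    initial = cfg$initial %||% list(),
    precip_chem = unlist(cfg$precip_chem) %||% numeric(0),
    dt = cfg$dt %||% 1,
    spinup_days = cfg$spinup_days %||% 365,
    seed = cfg$seed %||% 1,
    surface_reactions = isTRUE(cfg$options$surface_reactions),
    signed_q10 = isTRUE(cfg$options$signed_q10))
}

#' Disable kinetic reactions by id
#'
#' Returns a copy of the network without the named kinetic reactions, for
#' reaction-toggling numerical experiments.
#'
#' @param net An `rt_network`.
#' @param ids Character vector of kinetic reaction ids.
#' @return An `rt_network`.
#' @export
disable_reactions <- function(net, ids) {
  found <- character(0)
  for (z in names(net$kinetic)) {
    keep <- vapply(net$kinetic[[z]], function(r) !(r$id %in% ids), logical(1))
    found <- c(found, vapply(net$kinetic[[z]][!keep], `[[`, "", "id"))
    net$kinetic[[z]] <- net$kinetic[[z]][keep]
  }
  missing <- setdiff(ids, found)
  if (length(missing))
    stopf("reaction id(s) not in network: %s", paste(missing, collapse = ", "))
  net
}
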