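#' Shipped example configurations
#'
#' Ready-to-run simulation configurations for the two example reaction
#' networks shipped with the package:
#'
#' * the carbon network — shallow- and deep-zone soil respiration (Monod),
#'   DOC sorption (equilibrium), carbonate mineral dissolution (TST, with
#'   zone-specific stoichiometry: 1.1 Ca per mole in the shallow zone, 0.9 in
#'   the deep zone) and CO2 gas-aqueous exchange, with full carbonate
#'   speciation;
#' * the nitrogen network — soil N leaching, plant nitrate uptake and
#'   denitrification in both zones, nitrate being the only transported
#'   component.
#'
#' Both run on two years of synthetic humid-continental forcing over the
#' internal bucket hydrology. `overlay` entries modify the configuration,
#' e.g. `list(disable_reactions = "Denitrification_DZ")` for
#' reaction-toggling experiments.
#'
#' @param overlay Named list merged over the shipped config (see
#'   [read_sim_config()]).
#' @return An [sim_config()].
#' @export
carbon_example_config <- function(overlay = list()) {
  read_sim_config(catchrt_extdata("carbon.yml"), overlay)
}

#' @rdname carbon_example_config
#' @export
nitrogen_example_config <- function(overlay = list()) {
  read_sim_config(catchrt_extdata("nitrogen.yml"), overlay)
}

#' Path to a shipped data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the shipped files.
#' @return A file path.
#' @export
catchrt_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "catchrt")))
  p <- system.file("extdata", file, package = "catchrt")
  if (p == "") stopf("no shipped data file '%s'", file)
  p
}
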