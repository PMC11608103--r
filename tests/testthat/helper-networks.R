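# Small networks and forcing builders used across tests.

carbon_db <- function() {
  parse_database(readLines(catchrt_extdata("database.txt")))
}

carbon_net <- function() {
  build_network(catchrt_extdata("carbon_network.yml"), carbon_db())
}

nitrogen_net <- function() {
  build_network(catchrt_extdata("nitrogen_network.yml"), carbon_db())
}

# conservative tracer: one mobile primary, no reactions
tracer_net <- function() {
  build_network(list(species = list(primary = list("Tr"))), default_database())
}

# two-component toy with one complex: A + B = AB, log10 Keq = 0.5
toy_net <- function(logk = 0.5) {
  build_network(list(species = list(
    primary = list("A", "B"),
    secondary = list(AB = list(reaction = "A + B = AB", log10_keq = logk)))),
    default_database())
}

# carbonate system at fixed proton activity (pH pinned via a fixed-activity
# proton), for closed-form speciation checks
fixed_ph_carbonate_net <- function(a_h) {
  build_network(list(species = list(
    primary = list("HCO3-"),
    pseudo_gas = list("H+" = a_h),
    secondary = list(
      "CO2(aq)" = "CO2(aq) + H2O = H+ + HCO3-",
      "CO3--" = "HCO3- = CO3-- + H+"))),
    default_database())
}

# deterministic constant forcing (no snow, optionally no PET)
constant_forcing <- function(n_days, precip = 4, temp = 10, pet = 0,
                             chem = c(Tr = 1e-4)) {
  f <- tibble::tibble(date = seq_len(n_days), precip = precip, temp = temp,
                      pet = pet)
  for (s in names(chem)) f[[paste0("chem_", s)]] <- chem[[s]]
  f
}

# a speciation state pinned exactly at equilibrium of a TST reaction with
# log10 IAP = target: single solute "S", reaction M(s) -> S
tst_state_at <- function(log10_c) {
  net <- build_network(list(species = list(
    primary = list("S"), solid = list("M(s)"))), default_database())
  speciate(c(S = 10^log10_c), net$eqsys)
}
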