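# Nitrogen example simulation: nitrate production, uptake and
# denitrification on two years of synthetic forcing. Concentrations in mol/L.
dt: 1
spinup_days: 730
seed: 42
forcing:
  years: 2
  spec: {}
hbv: {tt: 0, cfmax: 3.5, fc: 250, lp: 0.7, beta: 2,
      k0: 0.3, k1: 0.1, k2: 0.01, uzl: 20, perc: 2.5}
zones: {sf_storage: 5, sz_depth: 2, sz_porosity: 0.45, sz_passive: 50,
        dz_depth: 6, dz_porosity: 0.2, dz_passive: 300, fc: 250}
network: nitrogen_network.yml
database: database.txt
precip_chem: {NO3-: 2.0e-5}
initial:
  SF: {NO3-: 2.0e-5}
  SZ: {NO3-: 2.0e-5}
  DZ: {NO3-: 3.0e-5}
options: {surface_reactions: false, signed_q10: true}
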