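# Carbon example simulation: two years of synthetic humid-continental
# forcing over the internal bucket hydrology, with the carbon reaction
# network. Concentrations in mol/L.
dt: 1
spinup_days: 365
seed: 42
forcing:
  years: 2
  spec: {}          # humid continental preset
hbv: {tt: 0, cfmax: 3.5, fc: 250, lp: 0.7, beta: 2,
      k0: 0.3, k1: 0.1, k2: 0.01, uzl: 20, perc: 2.5}
zones: {sf_storage: 5, sz_depth: 2, sz_porosity: 0.45, sz_passive: 200,
        dz_depth: 6, dz_porosity: 0.2, dz_passive: 500, fc: 250}
network: carbon_network.yml
database: database.txt
precip_chem: {DOC: 1.0e-5, HCO3-: 5.0e-6, Ca++: 2.0e-7, H+: 8.0e-6}
initial:
  SF: {DOC: 1.0e-5, HCO3-: 5.0e-6, Ca++: 2.0e-7, H+: 8.0e-6}
  SZ: {DOC: 1.7e-4, HCO3-: 1.4e-4, Ca++: 1.0e-6, H+: 1.0e-5, X: 0.5}
  DZ: {DOC: 1.0e-5, HCO3-: 2.0e-4, Ca++: 5.0e-6, H+: 1.0e-5}
options: {surface_reactions: false, signed_q10: true}
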