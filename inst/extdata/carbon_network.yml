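# Carbon example network: soil respiration, DOC sorption, carbonate
# weathering and CO2 gas-aqueous exchange in a two-subsurface-zone column.
# Inorganic carbon is carried on the bicarbonate component; DIC is the
# reported aggregate CO2(aq) + HCO3- + CO3--.
species:
  primary: [DOC, HCO3-, Ca++, H+]
  sorption_site: [X]
  secondary:
    CO2(aq): "CO2(aq) + H2O = H+ + HCO3-"
    CO3--: "HCO3- = CO3-- + H+"
    OH-: "H2O = H+ + OH-"
  sorbed:
    XDOC: "DOC + X = XDOC"
  solid: ["OC(s)", "OC_DZ(s)", "Carbonate_SZ(s)", "Carbonate_DZ(s)"]
  pseudo_gas:
    CO2(*g): 1.0
aggregates:
  DIC: ["CO2(aq)", "HCO3-", "CO3--"]
zones:
  SZ:
    kinetic:
      - id: Resp_SZ
        kind: monod
        # net DOC + DIC production from microbial processing of soil organic
        # carbon and root respiration/exudates (lumped substrate)
        reaction: "OC(s) -> 0.6 DOC + 0.55 HCO3-"
        log10_k: -10.2
        ssa: 0.10
        substrate: "OC(s)"
        substrate_mass: 150
        monod: {"OC(s)": 6.0e-6}
        q10: 2.3
        "n": 0.8
        swc: 0.7
        alpha_beta: 0
      - id: Carbonate_SZ
        kind: tst
        reaction: "Carbonate_SZ(s) -> 1.1 Ca++ + 0.5 HCO3-"
        substrate: "Carbonate_SZ(s)"
        substrate_mass: 0.05
        q10: 1.0
        "n": 1.0
        swc: 1.0
        alpha_beta: 0
      - id: CO2_exchange_SZ
        kind: tst
        reaction: "CO2(*g) = CO2(aq)"
        ssa: 0.01
        substrate: "CO2(*g)"
        substrate_mass: 1.0e+5
        q10: 3.0
        "n": 2.0
        swc: 0.7
        alpha_beta: 0
  DZ:
    kinetic:
      - id: Resp_DZ
        kind: monod
        # decomposition of translocated DOC (and petrogenic carbon) into DIC
        reaction: "OC_DZ(s) + DOC -> 0.7 HCO3-"
        log10_k: -9.2
        ssa: 0.07
        substrate: "OC_DZ(s)"
        substrate_mass: 3.5e+4
        monod: {DOC: 5.0e-3}
        q10: 1.0
        "n": 1.2
        swc: 0.6
        alpha_beta: 0
      - id: Carbonate_DZ
        kind: tst
        reaction: "Carbonate_DZ(s) -> 0.9 Ca++ + 0.7 HCO3-"
        substrate: "Carbonate_DZ(s)"
        substrate_mass: 1.0e+5
        q10: 3.0
        "n": 0.9
        swc: 1.0
        alpha_beta: 0
      - id: CO2_exchange_DZ
        kind: tst
        reaction: "CO2(*g) = CO2(aq)"
        ssa: 0.007
        substrate: "CO2(*g)"
        substrate_mass: 1.0e+6
        q10: 1.5
        "n": 0.0
        swc: 0.7
        alpha_beta: 0
substrate_conc:
  SZ: {"OC(s)": 1.0e-2}
  DZ: {"OC_DZ(s)": 1.0e-2}
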