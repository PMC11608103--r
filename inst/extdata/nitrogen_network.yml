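# Nitrogen example network: soil N leaching, plant nitrate uptake and
# denitrification, in both subsurface zones. Nitrate is the only transported
# component; substrate pools (soil N) and sinks (plant N, N2O) are
# fixed-activity phases.
species:
  primary: [NO3-]
  solid: ["soilN(s)", "PlantN(s)"]
  pseudo_gas:
    N2O(*g): 1.0
zones:
  SZ:
    kinetic:
      - id: NLeaching_SZ
        kind: monod
        # net nitrate production from soil organic matter decomposition,
        # nitrification and rock N weathering (lumped)
        reaction: "soilN(s) -> NO3-"
        log10_k: -15.0
        ssa: 5.5
        substrate: "soilN(s)"
        substrate_mass: 6.4e+4
        monod: {"soilN(s)": 6.0e-4}
        q10: 2.0
        "n": 1.0
        swc: 1.7
        alpha_beta: 0
      - id: PlantUptake_SZ
        kind: monod
        # zeroth-order in solutes: r = k A x environmental factors
        reaction: "NO3- -> PlantN(s)"
        log10_k: -13.4
        ssa: 3.0
        substrate: "PlantN(s)"
        substrate_mass: 1.2e+3
        q10: 1.5
        "n": 1.0
        swc: 1.25
        alpha_beta: 0
      - id: Denitrification_SZ
        kind: monod
        reaction: "NO3- -> N2O(*g)"
        log10_k: -12.8
        ssa: 1.0e-6
        substrate: "soilN(s)"
        substrate_mass: 6.4e+4
        monod: {"NO3-": 1.0e-6}
        q10: 1.0
        "n": 1.0
        swc: 0.0
        alpha_beta: 0
  DZ:
    kinetic:
      - id: NLeaching_DZ
        kind: monod
        reaction: "soilN(s) -> NO3-"
        log10_k: -15.0
        ssa: 1.0e-4
        substrate: "soilN(s)"
        substrate_mass: 1.0e+4
        monod: {"soilN(s)": 6.0e-4}
        q10: 1.0
        "n": 1.0
        swc: 0.0
        alpha_beta: 0
      - id: PlantUptake_DZ
        kind: monod
        reaction: "NO3- -> PlantN(s)"
        log10_k: -13.4
        ssa: 1.0e-4
        substrate: "PlantN(s)"
        substrate_mass: 1.0e+4
        q10: 2.5
        "n": 1.0
        swc: 0.0
        alpha_beta: 0
      - id: Denitrification_DZ
        kind: monod
        reaction: "NO3- -> N2O(*g)"
        log10_k: -12.8
        ssa: 3.0e-4
        substrate: "soilN(s)"
        substrate_mass: 4.0e+7
        monod: {"NO3-": 1.0e-6}
        q10: 1.5
        "n": 1.0
        swc: 0.0
        alpha_beta: 0
substrate_conc:
  SZ: {"soilN(s)": 1.0e-2}
  DZ: {"soilN(s)": 1.0e-2}
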