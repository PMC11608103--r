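# catchrt constants database (CrunchFlow-style dialect)
# carbonate speciation
reaction "CO2(aq) + H2O = H+ + HCO3-"  log10_keq = -6.35
reaction "HCO3- = CO3-- + H+"  log10_keq = -10.33
reaction "H2O = H+ + OH-"  log10_keq = -14
# DOC sorption on soil exchange sites
reaction "DOC + X = XDOC"  log10_keq = -1
# carbonate mineral dissolution, zone-specific stoichiometry (inorganic
# carbon carried on the bicarbonate component)
reaction "Carbonate_SZ(s) -> 1.1 Ca++ + 0.5 HCO3-"  log10_keq = -7.4  log10_k = -9.19  ssa = 1
reaction "Carbonate_DZ(s) -> 0.9 Ca++ + 0.7 HCO3-"  log10_keq = -7.4  log10_k = -9.19  ssa = 0.0008
# soil CO2 gas-aqueous exchange
reaction "CO2(*g) = CO2(aq)"  log10_keq = -3.2  log10_k = -13.1
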