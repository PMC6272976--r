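design: plackett-burman
units: real
run_column: run
dummy_columns: [D1, D2, D3]
responses:
  EA: U/mL
  BM: OD600
sd_columns:
  EA: EA_sd
  BM: BM_sd
factors:
  A: {label: kappa-carrageenan (g/L), center: 1.75, halfwidth: 0.75}
  B: {label: FOS (g/L), center: 1.0, halfwidth: 0.5}
  C: {label: tryptone (g/L), center: 1.0, halfwidth: 0.5}
  D: {label: factor D (g/L), center: 1.5, halfwidth: 0.5}
  E: {label: NaCl (g/L), center: 17.5, halfwidth: 7.5}
  F: {label: K2HPO4 (g/L), center: 0.2, halfwidth: 0.1}
  G: {label: MgSO4.7H2O (g/L), center: 0.2, halfwidth: 0.1}
  H: {label: CaCl2 (g/L), center: 0.2, halfwidth: 0.1}
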