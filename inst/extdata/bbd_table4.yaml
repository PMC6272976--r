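design: box-behnken
units: coded
run_column: run
dummy_columns: []
responses:
  EA: U/mL
  BM: OD600
sd_columns:
  EA: EA_sd
  BM: BM_sd
factors:
  X1: {label: kappa-carrageenan (g/L), center: 2.0, halfwidth: 1.0}
  X2: {label: NaCl (g/L), center: 20.0, halfwidth: 5.0}
  X3: {label: yeast extract (g/L), center: 1.0, halfwidth: 0.5}
  X4: {label: FOS (g/L), center: 1.0, halfwidth: 0.5}
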