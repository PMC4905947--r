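jacobian:
- - 1.0
  - -1.0
- - 3.0
  - -2.0
diffusion:
- 0.1
- 2.0
n_cells: 24.0
out_csv: modes.csv
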