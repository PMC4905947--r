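width: 32.0
height: 32.0
density: 0.35
seed: 42.0
n_generations: 125.0
rule: B3/S23
topology: torus
link_radius: 1.0
out_csv: census.csv
out_rle: final.rle
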