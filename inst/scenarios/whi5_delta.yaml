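name: whi5_delta
conditions:
  - {source: glucose, concentration: 2}
F_policy: curve
controller: g1s_molecular
g1s_preset: whi5_delta
target_cells: 50000
n_rep: 1
seed: 1
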