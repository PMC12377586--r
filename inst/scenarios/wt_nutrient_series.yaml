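name: wt_nutrient_series
conditions:
  - {source: ethanol, concentration: 2}
  - {source: glucose, concentration: 0.05}
  - {source: glucose, concentration: 0.1}
  - {source: glucose, concentration: 0.2}
  - {source: glucose, concentration: 0.5}
  - {source: glucose, concentration: 2}
  - {source: glucose, concentration: 5}
F_policy: curve
controller: timer
target_cells: 50000
n_rep: 1
seed: 1
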