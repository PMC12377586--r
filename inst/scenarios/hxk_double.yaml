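# Reduced-glycolysis mutant (hexokinase isoenzymes lost): k_cat_gly x 1/2
name: hxk_double
conditions:
  - {source: glucose, concentration: 2}
  - {source: ethanol, concentration: 2}
overlay: {k_cat_gly: 0.5}
F_policy: optimal
controller: timer
target_cells: 50000
n_rep: 1
seed: 1
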