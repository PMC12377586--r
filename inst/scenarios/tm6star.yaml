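# Reduced-glucose-transport mutant: transporter catalytic coefficient x 1/5
name: tm6star
conditions:
  - {source: glucose, concentration: 2}
  - {source: ethanol, concentration: 2}
overlay: {k_cat_hxt: 0.2}
F_policy: optimal
controller: timer
target_cells: 50000
n_rep: 1
seed: 1
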