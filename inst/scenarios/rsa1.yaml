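# Crippled ribosome biogenesis: reduced protein synthesis rate only
name: rsa1
conditions:
  - {source: glucose, concentration: 2}
interface_overlay: {K2: 0.6}
F_policy: curve
controller: timer
target_cells: 50000
n_rep: 1
seed: 1
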