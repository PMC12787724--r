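# Desk-scale run: reduced box, volume-scaled rod budget, 2e6 production steps
box_lengths: [24, 30, 24]
rod_N: 10
rod_class: thin
rod_ka: 250
n_steps: 2.0e6
save_stride: 200
equilibration: 2.0e5
seed: 1
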