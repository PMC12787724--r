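# Production-scale run (cluster scale: 1e8 steps, five replicas via seeds
# seed+0..seed+4; expect days of CPU time per replica)
box_lengths: [48, 54, 48]
rod_N: 10
rod_class: thin
rod_ka: 250
n_steps: 1.0e8
save_stride: 2000
equilibration: 2.0e5
seed: 1
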