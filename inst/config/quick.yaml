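# Desk-scale profile: coarse mesh and reduced conductivity grids
# (91 x 5 x 3 = 1365 training specifications). Completes the whole
# mesh -> dataset -> train -> evaluate chain in well under 15 minutes on
# one CPU while preserving the full partition enumeration.
domain:
  kind: disk
  radius: 10.0
electrodes:
  n: 10
  width: 2.0
  placement: ring  # belt = fixed 3.5 cm pitch (used by the ablation stage)
  pitch: 3.5
mesh:
  h: 0.5
layers:
  d0: 0.3
  L: 15
  roi: auto
protocol:
  current: 1.0
dataset:
  gamma_f: 1.0
  gamma_m: [2.0, 4.0, 6.0, 8.0, 10.0]
  gamma_r: [1.5, 5.5, 9.5]
  enforce_order: false
  noise: 0.0
mlp:
  hidden: [512, 256, 128, 64, 32]
  epochs: 600
  batch_size: 128
  lr: 0.001
  lr_halve_every: 150
  validation_split: 0.1
  target_rmse: 0.03
evaluate:
  l_m: 14
  gamma_m: 6.0
  gamma_r: 5.5
  min_jump: 0.3
seed: 1
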