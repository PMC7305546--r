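# Full-scale reference profile: circular imaging domain, complete
# conductivity grids (91 x 17 x 9 = 13923 training specifications),
# production mesh resolution. Expect hours of simulation time on one CPU.
domain:
  kind: disk
  radius: 10.0
electrodes:
  n: 10
  width: 2.0
  placement: ring  # belt = fixed 3.5 cm pitch (used by the ablation stage)
  pitch: 3.5
mesh:
  h: 0.3
layers:
  d0: 0.3
  L: 15
  roi: auto
protocol:
  current: 1.0
dataset:
  gamma_f: 1.0
  gamma_m: [2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0, 8.5, 9.0, 9.5, 10.0]
  gamma_r: [1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5]
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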