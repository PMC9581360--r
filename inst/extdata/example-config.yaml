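# Example experiment configuration: the bat-mimicking 36-pattern sweep at
# the default geometry, reduced training protocol.
geometry:
  delta_y: 2.45      # mm, 0.49 * lambda
  delta_z: 2.45
  lambda: 5          # mm (70 kHz echo)
sampling:
  dt: 1              # ms
  T_ms: 66
grid:
  theta_max: 60
  phi_max: 60
  n_theta: 23
  n_phi: 23
protocol:
  n_train_steps: 1000
  n_eval_steps: 50
  seed: 1
motions: all36
seeds: [1, 2, 3]
quantization_steps: [0, 1, 3]
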