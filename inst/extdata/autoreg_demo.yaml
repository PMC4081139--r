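# Demonstration run configuration: autoregulation model fitted to 10 noisy
# observations, three prediction scenarios, perturbation scan.
model: autoregulation
prior:
  lower: [1.0e-2, 1.0e-2]
  upper: [1.0e4, 1.0e4]
theta_true: {theta1: 10, theta2: 0.3}
observation_times: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
noise_fraction: 0.1
data: dataset.csv
seed: 1
sampler:
  n_chains: 3
  n_iterations: 15000
  burn_in: 5000
  thin: 30
  jitter_sd: 1.0e-4
  snooker_prob: 0.1
  full_gamma_prob: 0.1
  archive_update_stride: 10
uq:
  b: 2
  alpha: 0.95
  grid_size: 201
theta_ref: {theta1: 10, theta2: 0.3}
scenarios:
  low_start:
    y0: 1
    horizon: 10
  high_start:
    y0: 1.0e4
    horizon: 10
  strong_input:
    y0: 1
    input_scale: 7
    horizon: 10
verbosity: 0
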