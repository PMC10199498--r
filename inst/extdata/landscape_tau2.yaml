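parameters:
  alpha: 1.0e-6
  beta: 400
  delta: 2
  mu_s: 0.2
  mu_a: 0.015
  l: 1
  tau: 2
  gamma: 0.9
  epsilon: 0.85
  sigma: 600
  rho: 1.0e-4
  T: 4
traits:
  t0: 0
  tl: 0.5
initial:
  s_hat: 10000
  v_hat: 10000
run:
  n_seasons: 100
  t0_grid: [0.0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5]
  tl_grid: [0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5]
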