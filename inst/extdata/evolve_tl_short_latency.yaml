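parameters:
  alpha: 1.0e-6
  beta: 400
  delta: 2
  mu_s: 0.2
  mu_a: 0.015
  l: 1
  tau: 1.5
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
  trait: tl
  start: 0.5
  n_seasons: 150
  ess_n_seasons: 300
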