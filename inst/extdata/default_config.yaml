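# Reference parameterization of the seasonal host-parasite model.
# All rates share the (unspecified) model time unit; the latency period tau
# here is the long-latency scenario (one parasite generation per season).
parameters:
  alpha: 1.0e-6     # transmission rate, per parasite per time
  beta: 400         # parasites released per host death
  delta: 2          # free-living parasite decay rate
  mu_s: 0.2         # juvenile host death rate
  mu_a: 0.015       # adult host death rate
  l: 1              # maturation rate
  tau: 3            # parasite latency period
  gamma: 0.9        # parasite between-season survival
  epsilon: 0.85     # host between-season survival
  sigma: 600        # host fecundity
  rho: 1.0e-4       # density-dependence strength
  T: 4              # season length
traits:
  t0: 0
  tl: 0.5
initial:
  s_hat: 10000
  v_hat: 10000
run:
  n_seasons: 150
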