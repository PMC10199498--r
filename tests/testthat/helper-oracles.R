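# Independent oracles used across the suite.
#
# euler_season: fixed-step explicit Euler integration of the within-season
# delay system (resident + optional mutant), entirely independent of the
# package's adaptive integrator.  The delayed term is read off the stored
# solution grid (tau must be an integer multiple of h).
euler_season <- function(s_hat, v_hat, t0, tl, params, h = 1e-5,
                         s_hat_m = 0, t0m = t0, tlm = tl) {
  T <- params$T; tau <- params$tau
  n <- round(T / h)
  k_tau <- round(tau / h)
  stopifnot(abs(k_tau * h - tau) < 1e-12, abs(n * h - T) < 1e-9)
  s <- numeric(n + 1); a <- numeric(n + 1); v <- numeric(n + 1)
  sm <- numeric(n + 1); am <- numeric(n + 1)
  C <- 0; Cm <- 0
  v[1] <- v_hat
  burst <- params$alpha * params$beta * exp(-params$mu_s * tau)
  alpha <- params$alpha; mus <- params$mu_s; mua <- params$mu_a
  l <- params$l; delta <- params$delta
  for (i in 1:n) {
    t <- (i - 1) * h
    gr <- if (t >= t0 && t <= t0 + tl) 1 / tl else 0
    gm <- if (t >= t0m && t <= t0m + tlm) 1 / tlm else 0
    dly <- if (i > k_tau) v[i - k_tau] * (s[i - k_tau] + sm[i - k_tau]) else 0
    inf_r <- alpha * s[i] * v[i]
    inf_m <- alpha * sm[i] * v[i]
    s[i + 1] <- s[i] + h * (s_hat * gr - mus * s[i] - inf_r - l * s[i])
    a[i + 1] <- a[i] + h * (l * s[i] - mua * a[i])
    sm[i + 1] <- sm[i] + h * (s_hat_m * gm - mus * sm[i] - inf_m - l * sm[i])
    am[i + 1] <- am[i] + h * (l * sm[i] - mua * am[i])
    v[i + 1] <- v[i] + h * (burst * dly - delta * v[i])
    C <- C + h * inf_r
    Cm <- Cm + h * inf_m
  }
  list(s_T = s[n + 1], a_T = a[n + 1], v_T = v[n + 1],
       sm_T = sm[n + 1], am_T = am[n + 1], cum_inf = C, cum_inf_m = Cm)
}

# Brute-force quadrature of the disease-free survival-to-adulthood
# probability: average over the realized emergence window of
#   P(e) = int_e^T l exp(-(mu_s+l)(m-e)) exp(-mu_a(T-m)) dm
# computed by nested numerical integration (no closed form used).
phi_quadrature <- function(t0, tl, params) {
  T <- params$T
  if (t0 >= T) return(0)
  P <- function(e) sapply(e, function(ei)
    integrate(function(m) params$l * exp(-(params$mu_s + params$l) * (m - ei)) *
                exp(-params$mu_a * (T - m)),
              ei, T, rel.tol = 1e-12, abs.tol = 0)$value)
  integrate(P, t0, min(t0 + tl, T), rel.tol = 1e-11, abs.tol = 0)$value / tl
}

table1_params <- function(tau = 3) model_parameters(tau = tau)
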