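test_that("without hosts the parasite decays exponentially, exactly", {
  p <- model_parameters()
  fit <- integrate_season(season_boundary_state(0, 100),
                          phenology_traits(0, 0.5), p,
                          times = seq(0, 4, by = 0.5))
  expect_equal(fit$summary$v_T, 100 * exp(-p$delta * p$T), tolerance = 1e-6)
  # dense output is Hermite-interpolated between accepted steps
  expect_equal(fit$trajectory$v, 100 * exp(-p$delta * fit$trajectory$t),
               tolerance = 1e-6)
  expect_equal(fit$summary$a_T, 0)
  expect_equal(fit$summary$infections, 0)
})

test_that("the uninfected season is linear in the cohort and matches the closed form", {
  p <- model_parameters()
  tr <- phenology_traits(0.3, 1.2)
  ts <- seq(0, 4, by = 0.25)
  f1 <- integrate_season(season_boundary_state(1e4, 0), tr, p, times = ts)
  f2 <- integrate_season(season_boundary_state(2e4, 0), tr, p, times = ts)
  expect_equal(f2$summary$a_T, 2 * f1$summary$a_T, tolerance = 1e-9)
  expect_equal(f2$trajectory$s, 2 * f1$trajectory$s, tolerance = 1e-8)
  phi <- maturation_probability(tr, p)
  expect_equal(f1$summary$a_T, phi * 1e4, tolerance = 1e-6)
})

test_that("adaptive solver agrees with the fixed-step Euler oracle", {
  for (cs in list(list(tau = 3, t0 = 0, tl = 0.5, sh = 1e4, vh = 1e4),
                  list(tau = 3, t0 = 0.2, tl = 0.5, sh = 1e5, vh = 1e4),
                  list(tau = 1.5, t0 = 0, tl = 2, sh = 1e5, vh = 1e3))) {
    p <- table1_params(cs$tau)
    eu <- euler_season(cs$sh, cs$vh, cs$t0, cs$tl, p, h = 1e-5)
    fit <- integrate_season(season_boundary_state(cs$sh, cs$vh),
                            phenology_traits(cs$t0, cs$tl), p)
    expect_equal(fit$summary$a_T, eu$a_T, tolerance = 1e-4)
    expect_equal(fit$summary$v_T, eu$v_T, tolerance = 1e-4)
    expect_equal(fit$summary$infections, eu$cum_inf, tolerance = 1e-4)
  }
})

test_that("resident-plus-mutant system agrees with the Euler oracle", {
  p <- table1_params(3)
  eu <- euler_season(1e5, 1e4, 0, 0.5, p, h = 1e-5,
                     s_hat_m = 1, t0m = 0.5, tlm = 1)
  fit <- integrate_season_with_mutant(season_boundary_state(1e5, 1e4), 1,
                                      phenology_traits(0, 0.5),
                                      phenology_traits(0.5, 1), p)
  expect_equal(fit$summary$a_mT, eu$am_T, tolerance = 1e-4)
  expect_equal(fit$summary$a_T, eu$a_T, tolerance = 1e-4)
  expect_equal(fit$summary$v_T, eu$v_T, tolerance = 1e-4)
})

test_that("solver agrees with an independent deSolve::dede integration", {
  skip_if_not_installed("deSolve")
  p <- table1_params(3)
  # t0 > 0 keeps the delayed term identically zero around the delay onset,
  # where dede's lag bookkeeping needs a guard
  t0 <- 0.2; tl <- 0.5; s_hat <- 1e5; v_hat <- 1e4
  rhs <- function(t, y, parms) {
    g <- if (t >= t0 && t <= t0 + tl) 1 / tl else 0
    dly <- if (t >= p$tau + 0.05) {
      lv <- deSolve::lagvalue(t - p$tau); lv[1] * lv[3]
    } else 0
    list(c(s_hat * g - p$mu_s * y[1] - p$alpha * y[1] * y[3] - p$l * y[1],
           p$l * y[1] - p$mu_a * y[2],
           p$alpha * p$beta * exp(-p$mu_s * p$tau) * dly - p$delta * y[3]))
  }
  out <- deSolve::dede(c(0, 0, v_hat), c(0, p$T), rhs, NULL,
                       rtol = 1e-10, atol = 1e-8,
                       control = list(mxhist = 1e5))
  fit <- integrate_season(season_boundary_state(s_hat, v_hat),
                          phenology_traits(t0, tl), p)
  expect_equal(fit$summary$a_T, unname(out[2, 3]), tolerance = 1e-6)
  expect_equal(fit$summary$v_T, unname(out[2, 4]), tolerance = 1e-5)
})

test_that("a zero mutant cohort reduces exactly to the resident system", {
  p <- table1_params(3)
  b <- season_boundary_state(1e5, 1e4)
  tr <- phenology_traits(0, 0.5)
  plain <- integrate_season(b, tr, p)
  # different mutant traits change the breakpoint mesh, so agreement is to
  # solver tolerance, not bitwise
  withm <- integrate_season_with_mutant(b, 0, tr, phenology_traits(1, 2), p)
  expect_equal(withm$summary$a_T, plain$summary$a_T, tolerance = 1e-7)
  expect_equal(withm$summary$v_T, plain$summary$v_T, tolerance = 1e-7)
  expect_identical(withm$summary$a_mT, 0)
  # identical mutant traits reproduce the resident system bitwise
  same <- integrate_season_with_mutant(b, 0, tr, tr, p)
  expect_identical(same$summary$a_T, plain$summary$a_T)
  expect_identical(same$summary$v_T, plain$summary$v_T)
})

test_that("identical types are exchangeable: equal per-capita adult output", {
  p <- table1_params(3)
  tr <- phenology_traits(0, 0.5)
  s_star <- 3975921
  fit <- integrate_season_with_mutant(season_boundary_state(s_star, 1.8e8), 1,
                                      tr, tr, p)
  per_cap_res <- fit$summary$a_T / s_star
  expect_equal(fit$summary$a_mT, per_cap_res, tolerance = 1e-6)
})

test_that("parasites can only reduce host maturation", {
  p <- table1_params(3)
  tr <- phenology_traits(0, 0.5)
  a0 <- integrate_season(season_boundary_state(1e5, 0), tr, p)$summary$a_T
  for (vh in c(1e3, 1e5, 1e7)) {
    av <- integrate_season(season_boundary_state(1e5, vh), tr, p)$summary$a_T
    expect_lt(av, a0)
  }
  # and a later mutant does worse than the resident when parasites are absent
  fit <- integrate_season_with_mutant(season_boundary_state(1e5, 0), 1,
                                      phenology_traits(0.5, 0.5),
                                      phenology_traits(1.5, 0.5), p)
  expect_lt(fit$summary$a_mT, fit$summary$a_T / 1e5)
})

test_that("trajectories are nonnegative with nondecreasing cumulative infections", {
  p <- table1_params(1.5)
  ts <- seq(0, 4, by = 0.01)
  fit <- integrate_season(season_boundary_state(5e6, 1e6),
                          phenology_traits(0.3, 1.7), p, times = ts)
  tr <- fit$trajectory
  expect_true(all(tr$s >= 0) && all(tr$a >= 0) && all(tr$v >= 0))
  expect_true(all(diff(tr$cum_inf) >= -1e-8))
  expect_lte(fit$summary$infections, fit$summary$emerged)
  expect_gte(fit$summary$prevalence, 0)
  expect_lte(fit$summary$prevalence, 1)
})

test_that("invalid season setups are rejected", {
  p <- model_parameters()
  expect_error(integrate_season(season_boundary_state(1, 1),
                                phenology_traits(4.5, 0.5), p), "season length")
  expect_error(integrate_season_with_mutant(season_boundary_state(1, 1), -1,
                                            phenology_traits(0, 0.5),
                                            phenology_traits(0, 0.5), p),
               "mutant_cohort")
})
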