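test_that("a resident is selectively neutral against itself across trait space", {
  for (cs in list(c(1.5, 0, 0.5), c(1.5, 0.4, 2), c(3, 0, 0.5), c(3, 0.4, 2))) {
    p <- table1_params(cs[1])
    r <- phenology_traits(cs[2], cs[3])
    w <- invasion_fitness(r, r, p, n_seasons = 300)
    expect_equal(w$fitness, 1, tolerance = 1e-4)
    expect_true(w$invades || abs(w$fitness - 1) < 1e-4)
  }
})

test_that("without parasites later emergence cannot invade (beyond the flat start)", {
  p <- table1_params(3)
  init0 <- season_boundary_state(1e4, 0)
  r <- phenology_traits(0.5, 0.5)
  env <- equilibrium(r, p, initial = init0, n_seasons = 100)
  w_later <- invasion_fitness(phenology_traits(1, 0.5), r, p, env = env)
  expect_lt(w_later$fitness, 1)
  w_earlier <- invasion_fitness(phenology_traits(0.2, 0.5), r, p, env = env)
  expect_gt(w_earlier$fitness, 1)
  # matching selection gradient signs
  g <- selection_gradient("t0", r, p, env = env)
  expect_lt(g, 0)
})

test_that("parasites reverse selection on emergence start", {
  p <- table1_params(1.5)
  r <- phenology_traits(0, 0.5)
  g <- selection_gradient("t0", r, p, n_seasons = 300)
  expect_gt(g, 0)  # with short-latency parasites, later emergence is favored
})

test_that("selection gradient vanishes at a converged interior optimum", {
  p <- table1_params(3)
  # the disease-free landscape in t0 peaks where the window straddles the
  # survival-probability maximum; the gradient there is tiny
  r <- phenology_traits(0.04, 0.5)
  g <- selection_gradient("t0", r, p, n_seasons = 100,
                          initial = season_boundary_state(1e4, 0))
  expect_lt(abs(g), 1e-3)
})

test_that("ESS search without parasites settles at the early/short extreme", {
  p <- table1_params(3)
  init0 <- season_boundary_state(1e4, 0)
  e_a <- find_ess("t0", start = 0.5, params = p, initial = init0,
                  n_seasons = 60)
  e_b <- find_ess("t0", start = 1.5, params = p, initial = init0,
                  n_seasons = 60)
  expect_true(e_a$converged && e_b$converged)
  expect_lt(abs(e_a$value - e_b$value), 0.02)  # start-invariant
  expect_lt(e_a$value, 0.1)                    # at the flat early plateau
  e_tl <- find_ess("tl", start = 1.2, params = p, initial = init0,
                   n_seasons = 60, fixed_traits = phenology_traits(0, 0.5))
  expect_true(e_tl$converged)
  expect_lt(e_tl$value, 0.6)                   # near the minimum period length
})

test_that("pairwise invasibility is neutral on the diagonal and orders the disease-free landscape", {
  p <- table1_params(3)
  pip <- pairwise_invasibility("t0", c(0.5, 1, 1.5), p,
                               initial = season_boundary_state(1e4, 0),
                               n_seasons = 60)
  expect_equal(unname(diag(pip$fitness_matrix)), rep(1, 3), tolerance = 1e-4)
  # mutants earlier than the resident (below the diagonal) always invade
  m <- pip$fitness_matrix
  expect_true(all(m[row(m) > col(m)] > 1))
  expect_true(all(m[row(m) < col(m)] < 1))
})

test_that("mutual invasibility brackets the parasite-extinction boundary", {
  p <- table1_params(3)
  r_lo <- phenology_traits(0.85, 0.5)
  r_hi <- phenology_traits(0.95, 0.5)
  env_lo <- equilibrium(r_lo, p, n_seasons = 300)
  env_hi <- equilibrium(r_hi, p, n_seasons = 300)
  # parasites persist on the early resident and collapse on the late one
  expect_gt(env_lo$v_hat, 1e5)
  expect_lt(env_hi$v_hat, 1)
  w_up <- invasion_fitness(r_hi, r_lo, p, env = env_lo)
  w_dn <- invasion_fitness(r_lo, r_hi, p, env = env_hi)
  expect_gt(w_up$fitness, 1)
  expect_gt(w_dn$fitness, 1)
})

test_that("density landscape reproduces the closed form without parasites and never exceeds it with them", {
  p <- table1_params(2)
  t0g <- c(0, 1, 2); tlg <- c(0.5, 2)
  free <- density_landscape(t0g, tlg, p, n_seasons = 60, parasites = FALSE)
  for (i in seq_along(t0g)) for (j in seq_along(tlg))
    expect_equal(free$s_hat_matrix[i, j],
                 disease_free_equilibrium(phenology_traits(t0g[i], tlg[j]), p),
                 tolerance = 1e-4)
  withp <- density_landscape(t0g, tlg, p, n_seasons = 60, parasites = TRUE)
  expect_true(all(withp$s_hat_matrix <= free$s_hat_matrix * (1 + 1e-8)))
  # the disease-free maximum sits at the earliest, shortest emergence
  expect_equal(which.max(free$s_hat_matrix), 1L)
})

test_that("trait bounds and grids are validated", {
  p <- model_parameters()
  expect_error(find_ess("t0", start = 5, params = p), "bounds")
  expect_error(find_ess("width", start = 1, params = p), "trait_name")
  expect_error(pairwise_invasibility("t0", c(2, 1), p), "sorted")
  expect_error(selection_gradient("tl", phenology_traits(0, 0.5),
                                  p, h = 10), "bounds")
})
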