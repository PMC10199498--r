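# Evolutionary invasion analysis (adaptive dynamics) of the host phenology
# traits.  The environment a mutant experiences is set by the resident at its
# seasonal equilibrium; invasion fitness is the size of the cohort a single
# mutant founder contributes to the next season.

trait_bounds <- function(trait_name, params, tl_min = 0.5) {
  switch(trait_name,
         t0 = c(0, params$T),
         tl = c(tl_min, params$T),
         stop("trait_name must be 't0' or 'tl'", call. = FALSE))
}

set_trait <- function(traits, trait_name, value) {
  if (trait_name == "t0")
    phenology_traits(t0 = value, tl = traits$tl, tl_min = traits$tl_min)
  else
    phenology_traits(t0 = traits$t0, tl = value, tl_min = traits$tl_min)
}

resident_environment <- function(resident, params, n_seasons, initial,
                                 rtol, atol) {
  equilibrium(resident, params, initial = initial, n_seasons = n_seasons,
              rtol = rtol, atol = atol)
}

mutant_fitness_in_env <- function(mutant, resident, env, params, rtol, atol) {
  b <- season_boundary_state(env$s_hat, env$v_hat)
  fit <- integrate_season_with_mutant(b, 1, resident, mutant, params,
                                      rtol = rtol, atol = atol)
  # density dependence is set by the resident adults alone: the mutant is
  # rare (a measure-zero perturbation of the resident density), which also
  # makes resident-vs-self neutrality exact
  params$epsilon * params$sigma * fit$summary$a_mT /
    (1 + params$rho * fit$summary$a_T)
}

#' Mutant invasion fitness
#'
#' The number of next-season mutants produced by a single mutant host
#' introduced into the environment set by the resident at its seasonal
#' equilibrium.  The mutant invades when this is at least 1.  The mutant's
#' offspring experience the density dependence generated by the resident
#' adult population (the mutant itself is rare).
#'
#' @param mutant,resident \code{\link{phenology_traits}} of the invader and
#'   the established type.
#' @param params \code{\link{model_parameters}}.
#' @param env optional precomputed resident environment (an
#'   \code{equilibrium_fit}); computed from \code{resident} when NULL.
#' @param n_seasons seasons used to equilibrate the resident (the reference
#'   analyses use 300).
#' @param initial starting boundary state for the resident equilibration.
#' @param rtol,atol within-season integration tolerances.
#' @return An object of class \code{invasion_result}: list with
#'   \code{fitness}, \code{invades} (fitness >= 1), and
#'   \code{resident_equilibrium} (the \code{s_hat}, \code{v_hat} used).
#' @examples
#' \donttest{
#' p <- model_parameters(tau = 3)
#' r <- phenology_traits(0, 0.5)
#' invasion_fitness(phenology_traits(0.5, 0.5), r, p, n_seasons = 100)
#' }
#' @export
invasion_fitness <- function(mutant, resident, params, env = NULL,
                             n_seasons = 300L,
                             initial = season_boundary_state(1e4, 1e4),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(mutant, "phenology_traits"),
            inherits(resident, "phenology_traits"),
            inherits(params, "model_parameters"))
  if (is.null(env))
    env <- resident_environment(resident, params, n_seasons, initial,
                                rtol, atol)
  w <- mutant_fitness_in_env(mutant, resident, env, params, rtol, atol)
  structure(list(fitness = w, invades = w >= 1,
                 resident_equilibrium = c(s_hat = env$s_hat,
                                          v_hat = env$v_hat),
                 resident_converged = env$converged,
                 mutant = mutant, resident = resident),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Invasion fitness = %.6f (%s)\n", x$fitness,
              if (x$invades) "mutant invades" else "mutant excluded"))
  cat(sprintf("  resident environment: s_hat* = %.6g, v_hat* = %.6g\n",
              x$resident_equilibrium[["s_hat"]],
              x$resident_equilibrium[["v_hat"]]))
  invisible(x)
}

#' Selection gradient on a phenology trait
#'
#' Central finite difference of invasion fitness in the named trait around the
#' resident value (one-sided at a trait bound).
#'
#' @param trait_name \code{"t0"} or \code{"tl"}.
#' @param resident resident \code{\link{phenology_traits}}.
#' @param params \code{\link{model_parameters}}.
#' @param h probe step (> 0).
#' @inheritParams invasion_fitness
#' @return Signed gradient estimate (change in fitness per unit trait).
#' @export
selection_gradient <- function(trait_name, resident, params, h = 0.01,
                               env = NULL, n_seasons = 300L,
                               initial = season_boundary_state(1e4, 1e4),
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(h > 0)
  bounds <- trait_bounds(trait_name, params, resident$tl_min)
  x <- if (trait_name == "t0") resident$t0 else resident$tl
  up <- x + h <= bounds[2]
  dn <- x - h >= bounds[1]
  if (!up && !dn)
    stop("neither probe ", trait_name, " = ", x, " +/- ", h,
         " lies within the trait bounds", call. = FALSE)
  if (is.null(env))
    env <- resident_environment(resident, params, n_seasons, initial,
                                rtol, atol)
  f <- function(val)
    mutant_fitness_in_env(set_trait(resident, trait_name, val), resident,
                          env, params, rtol, atol)
  if (up && dn) (f(x + h) - f(x - h)) / (2 * h)
  else if (up) (f(x + h) - f(x)) / h
  else (f(x) - f(x - h)) / h
}

#' Find the evolutionarily stable phenology trait
#'
#' Trait-substitution search: at each iteration the resident is equilibrated,
#' mutants one probe step above and below the resident trait are tested, and
#' the resident moves by \code{step} in the direction of an invading mutant.
#' The search stops when neither probe invades (an ESS to resolution
#' \code{step}) or when a bound is active and the inward probe does not
#' invade.  One trait evolves at a time; the other stays fixed at its value in
#' \code{fixed_traits}.
#'
#' @param trait_name \code{"t0"} or \code{"tl"}.
#' @param start starting resident trait value.
#' @param params \code{\link{model_parameters}}.
#' @param fixed_traits \code{\link{phenology_traits}} supplying the
#'   non-evolving trait (defaults: t0 = 0, tl = 0.5).
#' @param step mutation step size per substitution.
#' @param h probe step for the invasion test (default: equal to \code{step}).
#' @param max_iter iteration cap; exceeding it returns an unconverged result.
#' @param invade_tol numerical guard: a probe invades when its fitness exceeds
#'   \code{1 + invade_tol}, protecting the search from drift on selectively
#'   neutral plateaus where fitness equals 1 to solver accuracy.
#' @inheritParams invasion_fitness
#' @return An object of class \code{ess_result}: list with \code{trait_name},
#'   \code{value} (the optimal trait), \code{trajectory} of visited resident
#'   values, \code{converged}, \code{note} (e.g. "boundary-flat" when the
#'   landscape is numerically neutral at the stopping point), and
#'   \code{resident_equilibrium_at_ess} (\code{s_hat}, \code{v_hat},
#'   \code{prevalence}).
#' @examples
#' \donttest{
#' p <- model_parameters(tau = 3)
#' # no parasites: earliest emergence is optimal
#' find_ess("t0", start = 1, params = p,
#'          initial = season_boundary_state(1e4, 0), n_seasons = 50)
#' }
#' @export
find_ess <- function(trait_name, start, params,
                     fixed_traits = phenology_traits(0, 0.5),
                     step = 0.01, h = step, max_iter = 1000L,
                     n_seasons = 300L,
                     initial = season_boundary_state(1e4, 1e4),
                     invade_tol = 1e-6, rtol = 1e-8, atol = 1e-10) {
  stopifnot(step > 0, h > 0)
  bounds <- trait_bounds(trait_name, params, fixed_traits$tl_min)
  if (start < bounds[1] || start > bounds[2])
    stop("start must lie within the trait bounds [", bounds[1], ", ",
         bounds[2], "]", call. = FALSE)
  x <- start
  traj <- x
  converged <- FALSE
  note <- ""
  env <- NULL
  for (it in seq_len(max_iter)) {
    resident <- set_trait(fixed_traits, trait_name, x)
    env <- resident_environment(resident, params, n_seasons, initial,
                                rtol, atol)
    f_probe <- function(val)
      mutant_fitness_in_env(set_trait(resident, trait_name, val), resident,
                            env, params, rtol, atol)
    f_up <- if (x + h <= bounds[2]) f_probe(x + h) else -Inf
    f_dn <- if (x - h >= bounds[1]) f_probe(x - h) else -Inf
    up_inv <- f_up > 1 + invade_tol
    dn_inv <- f_dn > 1 + invade_tol
    if (!up_inv && !dn_inv) {
      converged <- TRUE
      best <- max(f_up, f_dn)
      if (is.finite(best) && abs(best - 1) <= 10 * invade_tol)
        note <- "boundary-flat"
      break
    }
    dir <- if (up_inv && dn_inv) (if (f_up >= f_dn) 1 else -1)
           else if (up_inv) 1 else -1
    x_new <- min(bounds[2], max(bounds[1], x + dir * step))
    if (x_new == x) { converged <- TRUE; note <- "bound"; break }
    n_tr <- length(traj)
    if (n_tr >= 2 && abs(x_new - traj[n_tr - 1]) < step / 2) {
      # substitution sequence oscillates between two adjacent trait values:
      # the singular point lies between them (typical at the
      # parasite-extinction boundary); report the midpoint at resolution step
      x <- (x + x_new) / 2
      converged <- TRUE
      note <- sprintf("limit-cycle between %.6g and %.6g; midpoint reported",
                      min(traj[n_tr], x_new), max(traj[n_tr], x_new))
      traj <- c(traj, x)
      break
    }
    x <- x_new
    traj <- c(traj, x)
  }
  structure(list(
    trait_name = trait_name, value = x, trajectory = traj,
    converged = converged, note = note,
    resident_equilibrium_at_ess = c(s_hat = env$s_hat, v_hat = env$v_hat,
                                    prevalence = env$prevalence),
    fixed_traits = fixed_traits, step = step, h = h,
    n_seasons = n_seasons
  ), class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("ESS search on %s: %s* = %.2f (%s%s)\n", x$trait_name,
              x$trait_name, x$value,
              if (x$converged) "converged" else "NOT converged",
              if (nzchar(x$note)) paste0(", ", x$note) else ""))
  eq <- x$resident_equilibrium_at_ess
  cat(sprintf("  resident equilibrium: s_hat* = %.6g, v_hat* = %.6g, prevalence = %.4f\n",
              eq[["s_hat"]], eq[["v_hat"]], eq[["prevalence"]]))
  cat(sprintf("  %d substitutions from start %.2f\n",
              length(x$trajectory) - 1L, x$trajectory[1]))
  invisible(x)
}

#' Pairwise invasibility plot grid
#'
#' Invasion fitness for every (resident, mutant) pair over a trait grid.  The
#' diagonal is selectively neutral (fitness 1); sign changes of
#' \code{fitness - 1} across the diagonal locate singular strategies.
#'
#' @param trait_name \code{"t0"} or \code{"tl"}.
#' @param grid sorted vector of trait values within bounds.
#' @param params \code{\link{model_parameters}}.
#' @param fixed_traits \code{\link{phenology_traits}} supplying the
#'   non-evolving trait.
#' @inheritParams invasion_fitness
#' @return An object of class \code{pip_grid}: list with \code{resident_grid},
#'   \code{mutant_grid} and \code{fitness_matrix} (rows = residents, columns =
#'   mutants).
#' @export
pairwise_invasibility <- function(trait_name, grid, params,
                                  fixed_traits = phenology_traits(0, 0.5),
                                  n_seasons = 300L,
                                  initial = season_boundary_state(1e4, 1e4),
                                  rtol = 1e-8, atol = 1e-10) {
  bounds <- trait_bounds(trait_name, params, fixed_traits$tl_min)
  if (is.unsorted(grid) || any(grid < bounds[1]) || any(grid > bounds[2]))
    stop("grid must be sorted and lie within the trait bounds", call. = FALSE)
  m <- matrix(NA_real_, nrow = length(grid), ncol = length(grid),
              dimnames = list(resident = signif(grid, 8),
                              mutant = signif(grid, 8)))
  for (i in seq_along(grid)) {
    resident <- set_trait(fixed_traits, trait_name, grid[i])
    env <- resident_environment(resident, params, n_seasons, initial,
                                rtol, atol)
    for (j in seq_along(grid)) {
      mut <- set_trait(fixed_traits, trait_name, grid[j])
      m[i, j] <- mutant_fitness_in_env(mut, resident, env, params,
                                       rtol, atol)
    }
  }
  structure(list(trait_name = trait_name, resident_grid = grid,
                 mutant_grid = grid, fitness_matrix = m),
            class = "pip_grid")
}

#' @export
print.pip_grid <- function(x, ...) {
  cat(sprintf("Pairwise invasibility grid in %s: %d x %d\n", x$trait_name,
              nrow(x$fitness_matrix), ncol(x$fitness_matrix)))
  cat(sprintf("  fitness range [%.4f, %.4f], diagonal max |w - 1| = %.2e\n",
              min(x$fitness_matrix), max(x$fitness_matrix),
              max(abs(diag(x$fitness_matrix) - 1))))
  invisible(x)
}

#' Equilibrium host density over a phenology grid
#'
#' Equilibrium host cohort size for every combination of emergence start and
#' emergence period length, with or without parasites.
#'
#' @param t0_grid,tl_grid trait values spanning the grid.
#' @param params \code{\link{model_parameters}}.
#' @param n_seasons seasons run per cell (the reference contour uses 100).
#' @param parasites if FALSE the initial parasite density is 0.
#' @inheritParams invasion_fitness
#' @return An object of class \code{density_landscape}: list with the grids
#'   and \code{s_hat_matrix} (rows = t0, columns = tl); cells whose
#'   equilibration failed carry NA and are listed in \code{failures}.
#' @export
density_landscape <- function(t0_grid, tl_grid, params, n_seasons = 100L,
                              parasites = TRUE,
                              initial = season_boundary_state(1e4, 1e4),
                              rtol = 1e-8, atol = 1e-10) {
  init <- if (parasites) initial
          else season_boundary_state(initial$s_hat, 0)
  m <- matrix(NA_real_, nrow = length(t0_grid), ncol = length(tl_grid),
              dimnames = list(t0 = signif(t0_grid, 8),
                              tl = signif(tl_grid, 8)))
  failures <- list()
  for (i in seq_along(t0_grid)) for (j in seq_along(tl_grid)) {
    tr <- phenology_traits(t0_grid[i], tl_grid[j])
    res <- tryCatch(
      equilibrium(tr, params, initial = init, n_seasons = n_seasons,
                  rtol = rtol, atol = atol),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(t0 = t0_grid[i], tl = tl_grid[j],
             message = conditionMessage(res))
    } else m[i, j] <- res$s_hat
  }
  structure(list(t0_grid = t0_grid, tl_grid = tl_grid, s_hat_matrix = m,
                 parasites = parasites, n_seasons = n_seasons,
                 failures = failures),
            class = "density_landscape")
}
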