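# Within-season solver: method-of-steps integration of the delay system.
# The compiled backend restarts the Dormand-Prince integrator at every
# non-smooth point (emergence-window edges and all their latency shifts) and
# serves delayed terms from cubic-Hermite dense history.

season_summary_from_state <- function(state, boundary, traits, params,
                                      mutant_cohort = 0,
                                      mutant_traits = traits,
                                      with_mutant = mutant_cohort > 0) {
  emerged_frac <- function(tr) {
    if (tr$t0 >= params$T) return(0)
    min(1, (params$T - tr$t0) / tr$tl)
  }
  emerged <- boundary$s_hat * emerged_frac(traits)
  infections <- unname(state[["cum_inf"]])
  prev <- if (emerged > 0) min(1, infections / emerged) else 0
  out <- list(
    a_T = unname(state[["a"]]),
    v_T = unname(state[["v"]]),
    emerged = emerged,
    infections = infections,
    prevalence = prev
  )
  if (with_mutant) {
    emerged_m <- mutant_cohort * emerged_frac(mutant_traits)
    inf_m <- unname(state[["cum_inf_m"]])
    out$a_mT <- unname(state[["a_m"]])
    out$emerged_m <- emerged_m
    out$infections_m <- inf_m
    out$prevalence_m <- if (emerged_m > 0) min(1, inf_m / emerged_m) else 0
  }
  structure(out, class = "season_summary")
}

#' Integrate one season of the host-parasite delay system
#'
#' Solves the within-season dynamics on \[0, T\]: juveniles \code{s} emerge at
#' the phenology-determined rate and are lost to death, maturation and
#' infection; adults \code{a} accumulate by maturation; parasites \code{v}
#' decay and are replenished, after the latency period \code{tau}, by bursts
#' from hosts infected \code{tau} time units earlier (discounted by juvenile
#' survival through latency, \code{exp(-mu_s * tau)}).  Parasite loss to
#' transmission is neglected.  Infections initiated after \code{T - tau}
#' release no parasites within the season.  The season starts with no active
#' juveniles (\code{s(0) = 0}) and parasite density \code{v_hat}.
#'
#' @param boundary a \code{\link{season_boundary_state}}: the emerging cohort
#'   size and starting parasite density.
#' @param traits host \code{\link{phenology_traits}}.
#' @param params \code{\link{model_parameters}}.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param times optional numeric vector of output times in \[0, T\] at which a
#'   dense trajectory is returned.
#' @return An object of class \code{season_fit}: a list with \code{summary}
#'   (end-of-season adult and parasite densities \code{a_T}, \code{v_T}, the
#'   number of hosts that emerged, cumulative infections and prevalence =
#'   infections / emerged) and, when \code{times} is given, \code{trajectory}
#'   (a data frame with columns \code{t, s, a, v, cum_inf}).
#' @examples
#' fit <- integrate_season(season_boundary_state(1e4, 1e4),
#'                         phenology_traits(0, 0.5), model_parameters())
#' fit$summary$a_T
#' @export
integrate_season <- function(boundary, traits, params,
                             rtol = 1e-8, atol = 1e-10, times = NULL) {
  stopifnot(inherits(boundary, "season_boundary"),
            inherits(traits, "phenology_traits"),
            inherits(params, "model_parameters"))
  if (traits$t0 > params$T)
    stop("t0 must not exceed the season length T", call. = FALSE)
  res <- .season_integrate_cpp(boundary$s_hat, boundary$v_hat, 0,
                               traits$t0, traits$tl, traits$t0, traits$tl,
                               unclass(params), rtol, atol,
                               if (is.null(times)) numeric(0) else as.numeric(times))
  if (!res$ok)
    stop("within-season integration failed: ", res$message, call. = FALSE)
  out <- list(
    summary = season_summary_from_state(res$state_T, boundary, traits, params),
    boundary = boundary, traits = traits, params = params,
    breakpoints = res$breakpoints, n_steps = res$n_steps
  )
  if (!is.null(times)) {
    tr <- as.data.frame(res$trajectory)
    out$trajectory <- tr[, c("t", "s", "a", "v", "cum_inf")]
  }
  structure(out, class = "season_fit")
}

#' Integrate one season with a rare mutant host cohort
#'
#' Extends \code{\link{integrate_season}} with a second (mutant) host type
#' carrying its own phenology traits.  Resident and mutant juveniles share the
#' parasite pool: the delayed parasite-production term is driven by the sum of
#' resident and mutant infections.
#'
#' @inheritParams integrate_season
#' @param mutant_cohort size of the emerging mutant cohort (the invasion
#'   analysis uses 1).
#' @param resident_traits,mutant_traits \code{\link{phenology_traits}} of the
#'   two host types.
#' @return A \code{season_fit} whose summary additionally carries the mutant
#'   end-of-season adult density \code{a_mT}, emerged mutants and mutant
#'   infections; the trajectory (if requested) gains columns \code{s_m, a_m,
#'   cum_inf_m}.
#' @export
integrate_season_with_mutant <- function(boundary, mutant_cohort,
                                         resident_traits, mutant_traits,
                                         params, rtol = 1e-8, atol = 1e-10,
                                         times = NULL) {
  stopifnot(inherits(boundary, "season_boundary"),
            inherits(resident_traits, "phenology_traits"),
            inherits(mutant_traits, "phenology_traits"),
            inherits(params, "model_parameters"))
  if (!is.numeric(mutant_cohort) || length(mutant_cohort) != 1L ||
      !is.finite(mutant_cohort) || mutant_cohort < 0)
    stop("mutant_cohort must be a single finite number >= 0", call. = FALSE)
  if (resident_traits$t0 > params$T || mutant_traits$t0 > params$T)
    stop("t0 must not exceed the season length T", call. = FALSE)
  res <- .season_integrate_cpp(boundary$s_hat, boundary$v_hat, mutant_cohort,
                               resident_traits$t0, resident_traits$tl,
                               mutant_traits$t0, mutant_traits$tl,
                               unclass(params), rtol, atol,
                               if (is.null(times)) numeric(0) else as.numeric(times))
  if (!res$ok)
    stop("within-season integration failed: ", res$message, call. = FALSE)
  out <- list(
    summary = season_summary_from_state(res$state_T, boundary,
                                        resident_traits, params,
                                        mutant_cohort = mutant_cohort,
                                        mutant_traits = mutant_traits,
                                        with_mutant = TRUE),
    boundary = boundary, traits = resident_traits,
    mutant_traits = mutant_traits, mutant_cohort = mutant_cohort,
    params = params, breakpoints = res$breakpoints, n_steps = res$n_steps
  )
  if (!is.null(times)) out$trajectory <- as.data.frame(res$trajectory)
  structure(out, class = "season_fit")
}

#' @export
print.season_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Season fit: emerged %.6g hosts, a(T) = %.6g, v(T) = %.6g\n",
              s$emerged, s$a_T, s$v_T))
  cat(sprintf("  infections = %.6g, prevalence = %.4f\n",
              s$infections, s$prevalence))
  if (!is.null(s$a_mT))
    cat(sprintf("  mutant: a_m(T) = %.6g from cohort %.6g\n",
                s$a_mT, x$mutant_cohort))
  invisible(x)
}
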