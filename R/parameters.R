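#' Model parameters for the seasonal host-parasite system
#'
#' Constructs and validates the full parameter set of the within-season
#' transmission model and the between-season maps.  Defaults are the standard
#' parameterization used throughout the package's reference analyses.
#'
#' @param alpha transmission rate, per parasite per time.
#' @param beta number of parasites released upon death of an infected host.
#' @param delta decay rate of free-living parasites, per time.
#' @param mu_s juvenile host death rate, per time.
#' @param mu_a adult host death rate, per time.
#' @param l host maturation rate (juvenile to adult), per time.
#' @param tau parasite latency period: the delay between infection and the
#'   release of new parasites.  May exceed the season length \code{T}, in which
#'   case no parasite reproduction occurs within a season.
#' @param gamma parasite between-season survival probability, in \[0, 1\].
#' @param epsilon host between-season survival probability, in \[0, 1\].
#' @param sigma host fecundity: offspring per surviving adult.
#' @param rho strength of density dependence in host reproduction.
#' @param T season length.  Time units are unspecified (the model is
#'   dimensionless in time); all rates share the same unit.
#'
#' @return An object of class \code{model_parameters} (a validated named list).
#' @examples
#' p <- model_parameters()          # reference values, tau = 3
#' p2 <- model_parameters(tau = 1.5)
#' @export
model_parameters <- function(alpha = 1e-6, beta = 400, delta = 2,
                             mu_s = 0.2, mu_a = 0.015, l = 1, tau = 3,
                             gamma = 0.9, epsilon = 0.85, sigma = 600,
                             rho = 1e-4, T = 4) {
  p <- list(alpha = alpha, beta = beta, delta = delta, mu_s = mu_s,
            mu_a = mu_a, l = l, tau = tau, gamma = gamma, epsilon = epsilon,
            sigma = sigma, rho = rho, T = T)
  for (k in names(p)) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", k, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- c("alpha", "beta", "delta", "mu_s", "mu_a", "l", "tau",
                  "sigma", "rho", "T")
  for (k in strict_pos)
    if (p[[k]] <= 0)
      stop("parameter '", k, "' must be strictly positive", call. = FALSE)
  for (k in c("gamma", "epsilon"))
    if (p[[k]] < 0 || p[[k]] > 1)
      stop("parameter '", k, "' must lie in [0, 1]", call. = FALSE)
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Seasonal host-parasite model parameters\n")
  cat(sprintf("  transmission alpha = %g, burst size beta = %g, decay delta = %g\n",
              x$alpha, x$beta, x$delta))
  cat(sprintf("  death rates mu_s = %g (juvenile), mu_a = %g (adult); maturation l = %g\n",
              x$mu_s, x$mu_a, x$l))
  cat(sprintf("  latency tau = %g, season length T = %g\n", x$tau, x$T))
  cat(sprintf("  between seasons: gamma = %g (parasite), epsilon = %g (host), sigma = %g, rho = %g\n",
              x$gamma, x$epsilon, x$sigma, x$rho))
  invisible(x)
}

#' Host phenology traits
#'
#' The two evolving traits of the host: \code{t0}, the time within the season
#' at which juvenile emergence begins, and \code{tl}, the length of the
#' emergence period.  Emergence is uniform on \[t0, t0 + tl\]; hosts scheduled
#' to emerge after the end of the season simply never emerge.
#'
#' @param t0 emergence start time, \code{0 <= t0}.
#' @param tl emergence period length, \code{tl >= tl_min}.
#' @param tl_min hard lower bound on the emergence period length (default 0.5,
#'   the minimum considered in the reference analyses).
#'
#' @return An object of class \code{phenology_traits}.
#' @examples
#' phenology_traits(t0 = 0, tl = 0.5)
#' @export
phenology_traits <- function(t0 = 0, tl = 0.5, tl_min = 0.5) {
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("t0 must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(tl) || length(tl) != 1L || !is.finite(tl) || tl < tl_min)
    stop("tl must be a single finite number >= tl_min (= ", tl_min, ")",
         call. = FALSE)
  structure(list(t0 = t0, tl = tl, tl_min = tl_min),
            class = "phenology_traits")
}

#' @export
print.phenology_traits <- function(x, ...) {
  cat(sprintf("Host phenology: emergence start t0 = %g, period length tl = %g (tl_min = %g)\n",
              x$t0, x$tl, x$tl_min))
  invisible(x)
}

#' Season boundary state
#'
#' The discrete state carried across seasons: the size of the emerging host
#' cohort and the density of parasites present at the start of the season.
#'
#' @param s_hat size of the host cohort emerging this season (>= 0).
#' @param v_hat parasite density at the start of the season (>= 0).
#' @param n season index (integer >= 1).
#' @return An object of class \code{season_boundary}.
#' @export
season_boundary_state <- function(s_hat = 1e4, v_hat = 1e4, n = 1L) {
  if (!is.numeric(s_hat) || length(s_hat) != 1L || !is.finite(s_hat) || s_hat < 0)
    stop("s_hat must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(v_hat) || length(v_hat) != 1L || !is.finite(v_hat) || v_hat < 0)
    stop("v_hat must be a single finite number >= 0", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1", call. = FALSE)
  structure(list(s_hat = s_hat, v_hat = v_hat, n = n),
            class = "season_boundary")
}

#' @export
print.season_boundary <- function(x, ...) {
  cat(sprintf("Season %d boundary: host cohort s_hat = %g, parasites v_hat = %g\n",
              x$n, x$s_hat, x$v_hat))
  invisible(x)
}

#' Per-capita host emergence rate
#'
#' The emergence forcing function: a uniform density on \[t0, t0 + tl\].
#' Its integral over the season equals \code{min(1, (T - t0)/tl)}; when
#' \code{t0 + tl > T} the remainder of the cohort never emerges.
#'
#' @param t time(s) within the season (vectorized).
#' @param traits a \code{\link{phenology_traits}} object.
#' @return Emergence rate(s), per time: \code{1/tl} inside the window, 0 outside.
#' @examples
#' emergence_rate(c(0.2, 3), phenology_traits(0, 0.5))
#' @export
emergence_rate <- function(t, traits) {
  stopifnot(inherits(traits, "phenology_traits"))
  ifelse(t >= traits$t0 & t <= traits$t0 + traits$tl, 1 / traits$tl, 0)
}

#' Between-season host reproduction map
#'
#' Maps end-of-season adult density to the next season's emerging cohort via
#' density-dependent (Beverton-Holt type) reproduction discounted by
#' between-season survival: \code{epsilon * sigma * a_T / (1 + rho * a_T)}.
#'
#' @param a_T adult host density at the end of the season (>= 0).
#' @param params a \code{\link{model_parameters}} object.
#' @return Next season's cohort size; bounded above by \code{epsilon*sigma/rho}.
#' @export
next_season_cohort <- function(a_T, params) {
  stopifnot(inherits(params, "model_parameters"))
  if (any(!is.finite(a_T)) || any(a_T < 0))
    stop("a_T must be finite and >= 0", call. = FALSE)
  params$epsilon * params$sigma * a_T / (1 + params$rho * a_T)
}

#' Between-season parasite survival map
#'
#' @param v_T parasite density at the end of the season (>= 0).
#' @param params a \code{\link{model_parameters}} object.
#' @return Starting parasite density next season, \code{gamma * v_T}.
#' @export
next_season_parasites <- function(v_T, params) {
  stopifnot(inherits(params, "model_parameters"))
  if (any(!is.finite(v_T)) || any(v_T < 0))
    stop("v_T must be finite and >= 0", call. = FALSE)
  params$gamma * v_T
}
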