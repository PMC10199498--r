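# Closed-form disease-free results.  With no parasites the juvenile/adult
# subsystem is linear and the season map has an explicit fixed point; these
# expressions serve as an independent check on the numerical solver and as a
# fast disease-free equilibrium.

# Antiderivative (in emergence time e) of the probability that a host emerging
# at e is alive as an adult at the end of the season:
#   P(e) = l * exp(-mu_a (T-e)) * (1 - exp(-(mu_s + l - mu_a)(T-e))) / (mu_s + l - mu_a)
# with analytic limits at the degenerate parameter combinations.
maturation_antideriv <- function(e, params) {
  mus <- params$mu_s; mua <- params$mu_a; l <- params$l; T <- params$T
  k <- mus + l - mua
  if (abs(k) > 1e-9) {
    if (mua > 1e-12) {
      l / k * (exp(-mua * (T - e)) / mua - exp(-(mus + l) * (T - e)) / (mus + l))
    } else {
      # mu_a = 0: P(e) = l (1 - exp(-(mus+l)(T-e))) / (mus+l)
      l / (mus + l) * (e - exp(-(mus + l) * (T - e)) / (mus + l))
    }
  } else {
    # mu_s + l = mu_a: P(e) = l (T-e) exp(-mu_a (T-e))
    l * exp(-mua * (T - e)) * ((T - e) / mua + 1 / mua^2)
  }
}

#' Probability of surviving to adulthood by the end of the season
#'
#' In the absence of parasites, the probability that a random member of the
#' emerging cohort is alive as an adult at the end of the season.  A host
#' emerging at time \code{e} matures at rate \code{l} while dying at rate
#' \code{mu_s}, then dies as an adult at rate \code{mu_a}; the cohort average
#' integrates this over the uniform emergence window, with hosts scheduled to
#' emerge after \code{T} contributing zero.  Evaluated in closed form.
#'
#' @param traits host \code{\link{phenology_traits}}.
#' @param params \code{\link{model_parameters}}.
#' @return The maturation-survival probability \code{phi} in \[0, 1\];
#'   strictly decreasing in \code{t0}.
#' @examples
#' maturation_probability(phenology_traits(0, 0.5), model_parameters())
#' @export
maturation_probability <- function(traits, params) {
  stopifnot(inherits(traits, "phenology_traits"),
            inherits(params, "model_parameters"))
  t0 <- traits$t0; tl <- traits$tl; T <- params$T
  if (t0 >= T) return(0)
  e2 <- min(t0 + tl, T)
  phi <- (maturation_antideriv(e2, params) -
          maturation_antideriv(t0, params)) / tl
  min(1, max(0, phi))
}

#' Disease-free host equilibrium (closed form)
#'
#' With no parasites the end-of-season adult density is \code{phi * s_hat}
#' with \code{phi} from \code{\link{maturation_probability}}, and the season
#' map has the explicit fixed point
#' \code{s_hat* = (epsilon*sigma*phi - 1) / (rho*phi)} when
#' \code{epsilon*sigma*phi > 1}, else 0 (the host cannot replace itself).
#'
#' @inheritParams maturation_probability
#' @return The equilibrium host cohort size.
#' @examples
#' disease_free_equilibrium(phenology_traits(0, 0.5), model_parameters())
#' @export
disease_free_equilibrium <- function(traits, params) {
  phi <- maturation_probability(traits, params)
  R0 <- params$epsilon * params$sigma * phi
  if (R0 <= 1) return(0)
  (R0 - 1) / (params$rho * phi)
}
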