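# Configuration files and output writers.  Runs are fully deterministic (the
# model has no random component), so identical configs yield byte-identical
# outputs.

run_directive_defaults <- function() {
  list(n_seasons = 150L, rel_tol = 1e-6, n_max = 500L,
       rtol = 1e-8, atol = 1e-10, trait = "t0", step = 0.01, h = 0.01,
       ess_n_seasons = 300L)
}

#' Load a run configuration
#'
#' Reads a YAML configuration with sections \code{parameters} (all twelve
#' model parameters, required and validated), \code{traits} (\code{t0},
#' \code{tl}, optional \code{tl_min}), \code{initial} (\code{s_hat},
#' \code{v_hat}) and \code{run} (run directives).  Unknown keys anywhere are
#' rejected with an error naming the key; missing parameter keys are likewise
#' named.  The shipped default configuration
#' (\code{system.file("extdata", "default_config.yaml", package =
#' "hostpheno")}) carries the reference parameter values.
#'
#' @param path path to a YAML config file.
#' @return An object of class \code{run_config}: list with elements
#'   \code{parameters} (\code{\link{model_parameters}}), \code{traits}
#'   (\code{\link{phenology_traits}}), \code{initial}
#'   (\code{\link{season_boundary_state}}) and \code{run} (named list of run
#'   directives).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_sections <- c("parameters", "traits", "initial", "run")
  extra <- setdiff(names(raw), known_sections)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$parameters))
    stop("config is missing the 'parameters' section", call. = FALSE)

  par_keys <- c("alpha", "beta", "delta", "mu_s", "mu_a", "l", "tau",
                "gamma", "epsilon", "sigma", "rho", "T")
  miss <- setdiff(par_keys, names(raw$parameters))
  if (length(miss))
    stop("config parameters section is missing required key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw$parameters), par_keys)
  if (length(extra))
    stop("unknown parameter key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  params <- do.call(model_parameters, raw$parameters)

  tr <- raw$traits
  if (!is.null(tr)) {
    extra <- setdiff(names(tr), c("t0", "tl", "tl_min"))
    if (length(extra))
      stop("unknown traits key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
  }
  traits <- do.call(phenology_traits, if (is.null(tr)) list() else tr)

  ini <- raw$initial
  if (!is.null(ini)) {
    extra <- setdiff(names(ini), c("s_hat", "v_hat"))
    if (length(extra))
      stop("unknown initial key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
  }
  initial <- do.call(season_boundary_state,
                     if (is.null(ini)) list() else ini)

  run <- run_directive_defaults()
  optional_run_keys <- c("t0_grid", "tl_grid", "parasites", "start")
  if (!is.null(raw$run)) {
    extra <- setdiff(names(raw$run), c(names(run), optional_run_keys))
    if (length(extra))
      stop("unknown run key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    run <- modifyList(run, raw$run)
  }
  if (!run$trait %in% c("t0", "tl"))
    stop("run$trait must be 't0' or 'tl'", call. = FALSE)

  structure(list(parameters = params, traits = traits, initial = initial,
                 run = run),
            class = "run_config")
}

#' Save a run configuration
#'
#' Writes a \code{run_config} back to YAML; \code{\link{load_config}} of the
#' result reproduces the configuration exactly.
#'
#' @param config a \code{run_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(
    parameters = unclass(config$parameters),
    traits = unclass(config$traits),
    initial = unclass(config$initial)[c("s_hat", "v_hat")],
    run = config$run
  ), path, precision = 15L)
  invisible(path)
}

#' Write a season series to CSV
#'
#' @param series a \code{season_series} from \code{\link{run_seasons}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_season_series <- function(series, path) {
  stopifnot(inherits(series, "season_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a within-season trajectory to CSV
#'
#' @param fit a \code{season_fit} computed with output \code{times}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  stopifnot(inherits(fit, "season_fit"))
  if (is.null(fit$trajectory))
    stop("season_fit has no stored trajectory; pass `times` to the solver",
         call. = FALSE)
  write.csv(fit$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Write an equilibrium record to JSON
#'
#' @param eq an \code{equilibrium_fit}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_equilibrium_json <- function(eq, path) {
  stopifnot(inherits(eq, "equilibrium_fit"))
  jsonlite::write_json(list(
    s_hat = eq$s_hat, v_hat = eq$v_hat, prevalence = eq$prevalence,
    a_T = eq$a_T, v_T = eq$v_T, n_used = eq$n_used,
    converged = eq$converged, parasites_extinct = eq$parasites_extinct
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an ESS result to JSON
#'
#' @param ess an \code{ess_result} from \code{\link{find_ess}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ess_json <- function(ess, path) {
  stopifnot(inherits(ess, "ess_result"))
  jsonlite::write_json(list(
    trait_name = ess$trait_name, value = ess$value,
    converged = ess$converged, note = ess$note,
    trajectory = ess$trajectory,
    resident_equilibrium_at_ess = as.list(ess$resident_equilibrium_at_ess)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a pairwise invasibility grid to CSV
#'
#' The matrix is written with the resident values as a leading column and the
#' mutant values as the header row.
#'
#' @param pip a \code{pip_grid}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pip <- function(pip, path) {
  stopifnot(inherits(pip, "pip_grid"))
  df <- data.frame(resident = pip$resident_grid, pip$fitness_matrix,
                   check.names = FALSE)
  names(df) <- c("resident", paste0("mutant_", signif(pip$mutant_grid, 8)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$parameters)
  print(x$traits)
  print(x$initial)
  cat("  run directives: ",
      paste(names(x$run), unlist(x$run), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
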