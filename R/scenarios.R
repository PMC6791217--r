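table1_rates <- function() {
  list(r = 0.206, K = 2139, rho = 0.2145, delta = 0.5115, gamma = 0.001)
}

#' Preset scenarios
#'
#' The five benchmark scenarios of the model. All use the reference rate
#' constants (r = 0.206, K = 2139, rho = 0.2145, delta = 0.5115,
#' gamma = 0.001), initial point (127, 0, 30), and a burst size solved from
#' the scenario's target reproduction number:
#' \describe{
#' \item{fig3}{subthreshold multi-delay case, \eqn{R_0 = 0.7}; transmission
#'   (1e-3, 0), (1e-5, 0.2), (2e-5, 1), (3e-5, 2), (4e-5, 3). Therapy fails;
#'   the tumor regrows to carrying capacity.}
#' \item{fig4}{same transmission spectrum with \eqn{R_0 = 1.5}; converges to
#'   the endemic equilibrium.}
#' \item{fig5}{single-delay case (1e-5, 0) + (1e-4, 7), \eqn{R_0 = 1.5};
#'   the delay is below the Hopf point, oscillations damp out.}
#' \item{fig6}{as fig5 with the delay at the printed critical value 8.8368
#'   (stored as given, so the preset is a fixed, citable input).}
#' \item{fig7}{as fig5 with delay 10, above the Hopf point; sustained
#'   oscillations.}
#' }
#'
#' @param name one of \code{"fig3"}, \code{"fig4"}, \code{"fig5"},
#'   \code{"fig6"}, \code{"fig7"}.
#' @return A list of class \code{virotherapy_scenario}: \code{name},
#'   \code{params}, \code{history}, \code{solver} (a list with \code{t_end},
#'   \code{rel_tol}, \code{abs_tol}).
#' @examples
#' sc <- scenario_preset("fig3")
#' reproduction_number(sc$params)
#' @export
scenario_preset <- function(name = c("fig3", "fig4", "fig5", "fig6", "fig7")) {
  name <- match.arg(name)
  rates <- table1_rates()
  multi <- tibble::tibble(beta = c(1e-3, 1e-5, 2e-5, 3e-5, 4e-5),
                          tau = c(0, 0.2, 1, 2, 3))
  single <- function(tau) tibble::tibble(beta = c(1e-5, 1e-4), tau = c(0, tau))
  spec <- switch(name,
    fig3 = list(r0 = 0.7, trans = multi, t_end = 2000),
    fig4 = list(r0 = 1.5, trans = multi, t_end = 2000),
    fig5 = list(r0 = 1.5, trans = single(7), t_end = 3000),
    fig6 = list(r0 = 1.5, trans = single(8.8368), t_end = 3000),
    fig7 = list(r0 = 1.5, trans = single(10), t_end = 3000))
  params <- virotherapy_params(r = rates$r, K = rates$K, rho = rates$rho,
                               delta = rates$delta, gamma = rates$gamma,
                               r0 = spec$r0, transmission = spec$trans)
  structure(
    list(name = name, params = params,
         history = c(x = 127, y = 0, v = 30),
         solver = list(t_end = spec$t_end, rel_tol = 1e-8, abs_tol = 1e-10)),
    class = "virotherapy_scenario")
}

#' @export
print.virotherapy_scenario <- function(x, ...) {
  cat(sprintf("<virotherapy_scenario> %s (R0 = %.4g, t_end = %g)\n",
              x$name, reproduction_number(x$params), x$solver$t_end))
  invisible(x)
}

#' Seeded random scenario fixtures
#'
#' Deterministic-in-seed parameter sets for property testing: rate constants
#' are jittered multiplicatively around the reference values, a delay
#' spectrum with the requested number of positive delays is drawn, and the
#' burst size is solved for a reproduction number drawn uniformly from
#' \code{r0_range}, so fixtures can be generated on either side of the
#' \eqn{R_0 = 1} threshold at will.
#'
#' @param seed integer seed; the same seed always yields the identical
#'   scenario.
#' @param r0_range range from which the target \eqn{R_0} is drawn.
#' @param n_delays number of positive-delay transmission terms.
#' @param jitter relative half-width of the uniform rate jitter.
#' @param include_instantaneous add a \eqn{\tau = 0} term.
#' @return A \code{virotherapy_scenario} (solver horizon 500 days).
#' @export
random_scenario <- function(seed, r0_range = c(1.1, 3), n_delays = 2,
                            jitter = 0.2, include_instantaneous = TRUE) {
  stopifnot(length(r0_range) == 2, all(r0_range > 0), n_delays >= 0)
  rates <- table1_rates()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  jit <- function(x) x * stats::runif(1, 1 - jitter, 1 + jitter)
  n_inst <- as.integer(include_instantaneous)
  n_terms <- n_delays + n_inst
  if (n_terms == 0L) stop("at least one transmission term required", call. = FALSE)
  betas <- 10^stats::runif(n_terms, -5, -3)
  taus <- if (n_delays > 0) sort(stats::runif(n_delays, 0.1, 10)) else numeric(0)
  trans <- tibble::tibble(beta = betas,
                          tau = c(if (n_inst) 0, taus))
  target_r0 <- stats::runif(1, r0_range[1], r0_range[2])
  params <- virotherapy_params(r = jit(rates$r), K = jit(rates$K),
                               rho = jit(rates$rho), delta = jit(rates$delta),
                               gamma = jit(rates$gamma),
                               r0 = target_r0, transmission = trans)
  history <- c(x = stats::runif(1, 10, 0.5 * params$K), y = 0,
               v = stats::runif(1, 1, 100))
  structure(
    list(name = sprintf("random-%d", seed), params = params,
         history = history,
         solver = list(t_end = 500, rel_tol = 1e-8, abs_tol = 1e-10),
         target_r0 = target_r0, seed = seed),
    class = "virotherapy_scenario")
}

#' Run a scenario
#'
#' Convenience wrapper: integrates a scenario with its stored solver
#' settings (overridable).
#'
#' @param scenario a \code{virotherapy_scenario}.
#' @param t_end optional horizon override (days).
#' @param ... passed to \code{\link{simulate_virotherapy}}.
#' @return A \code{virotherapy_trajectory}.
#' @export
run_scenario <- function(scenario, t_end = NULL, ...) {
  stopifnot(inherits(scenario, "virotherapy_scenario"))
  simulate_virotherapy(scenario$params, scenario$history,
                       t_end = if (is.null(t_end)) scenario$solver$t_end else t_end,
                       rel_tol = scenario$solver$rel_tol,
                       abs_tol = scenario$solver$abs_tol, ...)
}

scenario_to_list <- function(scenario) {
  list(name = scenario$name,
       params = params_to_list(scenario$params),
       history = as.list(scenario$history),
       solver = scenario$solver)
}

scenario_from_list <- function(x) {
  structure(
    list(name = x$name %||% "unnamed",
         params = params_from_list(x$params),
         history = c(x = as.numeric(x$history$x),
                     y = as.numeric(x$history$y),
                     v = as.numeric(x$history$v)),
         solver = list(t_end = as.numeric(x$solver$t_end %||% 2000),
                       rel_tol = as.numeric(x$solver$rel_tol %||% 1e-8),
                       abs_tol = as.numeric(x$solver$abs_tol %||% 1e-10))),
    class = "virotherapy_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write scenario configuration files
#'
#' Scenarios serialize to YAML (or JSON) with scalar parameter keys
#' \code{r, K, rho, delta, b, gamma}, a \code{transmission} list of
#' \code{{beta, tau}} records, and \code{history} / \code{solver} blocks.
#' Round-trips are lossless.
#'
#' @param scenario a \code{virotherapy_scenario}.
#' @param path file path; format chosen by extension (\code{.yaml},
#'   \code{.yml} or \code{.json}).
#' @return \code{write_scenario_config} returns the path invisibly;
#'   \code{read_scenario_config} returns the scenario.
#' @export
write_scenario_config <- function(scenario, path) {
  x <- scenario_to_list(scenario)
  # 17 significant digits: lossless for doubles
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  } else {
    yaml::write_yaml(x, path, precision = 17)
  }
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else yaml::read_yaml(path)
  scenario_from_list(x)
}
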