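#' Lyapunov functional along a trajectory
#'
#' Evaluates the functional certifying global stability of the
#' therapy-failure equilibrium when \eqn{R_0 < 1}:
#' \deqn{V(t) = b\,y(t) + v(t) +
#'       b \sum_i \beta_i \int_{t-\tau_i}^{t} x(s) v(s)\, ds,}
#' with the integrals computed by adaptive quadrature on the dense
#' trajectory. The time derivative is estimated by a central difference
#' (one-sided at the span ends). Along solutions the derivative satisfies
#' \eqn{\dot V = (b-1)\beta x v - \gamma v} exactly; bounding \eqn{x \le K}
#' gives \eqn{\dot V \le b\beta K (1 - 1/R_0)\, v(t)} when \eqn{b \ge 1},
#' and \eqn{\dot V \le -\gamma v(t)} when \eqn{b < 1}. The applicable
#' algebraic bound is returned alongside the numeric estimate; it is
#' negative for \eqn{v > 0} whenever \eqn{R_0 < 1}.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param traj a \code{virotherapy_trajectory} for these parameters.
#' @param t evaluation time(s); the window \eqn{[t - \tau_{max}, t]} must lie
#'   inside the trajectory span, i.e. \eqn{0 \le t \le t_{end}}.
#' @param diff_step central-difference step for the derivative estimate.
#' @param quad_tol quadrature tolerance for the memory integrals.
#' @return A tibble with columns \code{t}, \code{V}, \code{V_dot} and
#'   \code{V_dot_bound}.
#' @export
lyapunov_value <- function(params, traj, t, diff_step = 1e-3,
                           quad_tol = 1e-10) {
  stopifnot(inherits(params, "virotherapy_params"),
            inherits(traj, "virotherapy_trajectory"))
  if (any(t < 0) || any(t > traj$t_end))
    stop("the window [t - tau_max, t] must lie inside the trajectory span",
         call. = FALSE)
  betas <- params$transmission$beta
  taus <- params$transmission$tau
  b <- params$b

  xv <- function(s) {
    st <- trajectory_at(traj, s)
    st$x * st$v
  }
  V_of <- function(tt) {
    st <- trajectory_at(traj, tt)
    memory <- sum(purrr::map2_dbl(betas, taus, function(beta, tau) {
      if (tau == 0 || beta == 0) return(0)
      beta * stats::integrate(xv, tt - tau, tt, rel.tol = quad_tol,
                              abs.tol = quad_tol,
                              subdivisions = 500L)$value
    }))
    b * st$y + st$v + b * memory
  }
  purrr::map_dfr(t, function(tt) {
    V <- V_of(tt)
    lo <- max(0, tt - diff_step)
    hi <- min(traj$t_end, tt + diff_step)
    V_dot <- (V_of(hi) - V_of(lo)) / (hi - lo)
    vt <- trajectory_at(traj, tt)$v
    bound_rate <- if (b >= 1)
      b * beta_total(params) * params$K * (1 - 1 / reproduction_number(params))
    else -params$gamma
    bound <- bound_rate * vt
    tibble::tibble(t = tt, V = V, V_dot = V_dot, V_dot_bound = bound)
  })
}

#' Check monotone decrease of the Lyapunov functional
#'
#' When \eqn{R_0 < 1} the functional of \code{\link{lyapunov_value}} is
#' nonincreasing along every nonnegative solution; this check evaluates it
#' on a time grid and reports the worst increase relative to the tolerance
#' \code{1e-8 * max(V)}. When \eqn{R_0 \ge 1} the theory makes no claim and
#' the verdict is \code{"not applicable"}.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param traj a \code{virotherapy_trajectory} for these parameters.
#' @param grid evaluation times (default: 100 points over the span).
#' @return A list with \code{verdict} (\code{"pass"}, \code{"fail"} or
#'   \code{"not applicable"}), \code{worst_increase} and \code{tolerance}.
#' @export
lyapunov_monotone_check <- function(params, traj, grid = NULL) {
  r0 <- reproduction_number(params)
  if (r0 >= 1)
    return(list(verdict = "not applicable", worst_increase = NA_real_,
                tolerance = NA_real_, r0 = r0))
  if (is.null(grid))
    grid <- seq(0, traj$t_end, length.out = 100)
  vals <- lyapunov_value(params, traj, grid)
  tol <- 1e-8 * max(vals$V)
  inc <- diff(vals$V)
  worst <- max(c(inc, -Inf))
  list(verdict = if (all(inc <= tol)) "pass" else "fail",
       worst_increase = worst, tolerance = tol, r0 = r0, track = vals)
}

#' Time to tumor eradication
#'
#' First time at which the total tumor load \eqn{x(t) + y(t)} drops to the
#' threshold; with populations in units of \eqn{10^6} cells the default
#' threshold 1 corresponds to a single remaining cell, the conventional
#' criterion for complete elimination. Located by bisection on the dense
#' trajectory.
#'
#' @param traj a \code{virotherapy_trajectory}.
#' @param threshold load threshold (10^6 cells, > 0).
#' @return First crossing time (days), or \code{NA} if the load never
#'   reaches the threshold.
#' @export
eradication_time <- function(traj, threshold = 1) {
  stopifnot(inherits(traj, "virotherapy_trajectory"), threshold > 0)
  load <- traj$data$x + traj$data$y
  below <- which(load <= threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(traj$data$t[1])
  f <- function(s) {
    st <- trajectory_at(traj, s)
    st$x + st$y - threshold
  }
  stats::uniroot(f, c(traj$data$t[i - 1], traj$data$t[i]),
                 tol = 1e-10)$root
}

#' Summarize a simulated scenario
#'
#' Determines what the trajectory converged to — extinction \eqn{E_0},
#' therapy failure \eqn{E_1}, the endemic equilibrium \eqn{E^*} (terminal
#' distance below \eqn{10^{-3} K} in max norm), a sustained cycle (late
#' peak-to-trough amplitudes agreeing within 5\%), or none of these — along
#' with the eradication time and the extrema of the total tumor load.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param traj a \code{virotherapy_trajectory} for these parameters.
#' @return A list of class \code{scenario_summary}: \code{terminal_state},
#'   \code{converged_to}, \code{eradication_time}, \code{tumor_load_extrema},
#'   \code{oscillation} (metrics of the late window).
#' @export
summarize_trajectory <- function(params, traj) {
  stopifnot(inherits(params, "virotherapy_params"),
            inherits(traj, "virotherapy_trajectory"))
  terminal <- terminal_state(traj)
  eq <- equilibria(params)
  dists <- purrr::pmap_dbl(eq[, c("x", "y", "v")], function(x, y, v)
    max(abs(terminal - c(x, y, v))))
  tol <- 1e-3 * params$K
  late <- c(0.7 * traj$t_end, traj$t_end)
  osc <- oscillation_metrics(traj, "x", window = late)

  converged_to <- if (any(dists < tol)) {
    eq$equilibrium[which.min(dists)]
  } else if (osc$n_peaks >= 4L) {
    df <- traj$data[traj$data$t >= late[1], ]
    ex <- find_extrema(df$t, df$x)
    amps <- purrr::map_dbl(seq_len(nrow(ex$peaks)), function(i) {
      nxt <- ex$troughs$t > ex$peaks$t[i]
      if (!any(nxt)) return(NA_real_)
      ex$peaks$value[i] - ex$troughs$value[which(nxt)[1]]
    })
    amps <- utils::tail(amps[!is.na(amps)], 5)
    if (length(amps) >= 2 && max(amps) / min(amps) - 1 <= 0.05) "cycle"
    else "none"
  } else "none"

  load <- traj$data$x + traj$data$y
  structure(
    list(terminal_state = terminal, converged_to = converged_to,
         eradication_time = eradication_time(traj),
         tumor_load_extrema = c(min = min(load), max = max(load)),
         oscillation = osc,
         r0 = reproduction_number(params)),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("<scenario_summary>\n")
  cat(sprintf("  R0 = %.4g; converged to: %s\n", x$r0, x$converged_to))
  cat(sprintf("  terminal state: x = %.6g, y = %.3g, v = %.3g\n",
              x$terminal_state[["x"]], x$terminal_state[["y"]],
              x$terminal_state[["v"]]))
  if (!is.na(x$eradication_time))
    cat(sprintf("  tumor eradicated at t = %.4g d\n", x$eradication_time))
  invisible(x)
}
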