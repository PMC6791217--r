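#' Integrate the delayed virotherapy model
#'
#' Solves the multi-delay system forward from a constant history: the state
#' on \eqn{[-\tau_{max}, 0]} is held at the supplied initial point
#' \eqn{(x_0, y_0, v_0)}, the standard reading of point initial conditions
#' for delay systems. Integration uses an adaptive multistep solver with
#' interpolated access to the computed past (\code{deSolve::dede}); the
#' first-generation delay breakpoints \eqn{\tau_1, \dots, \tau_n}, where the
#' derivative is discontinuous, are forced onto the output mesh. With all
#' delays zero the system degenerates to a plain ODE and is integrated as
#' such.
#'
#' Negative-state excursions beyond \code{abs_tol} and blow-up (state norm
#' exceeding \eqn{10^6 K}) abort with a diagnostic rather than being clamped,
#' so solver misconfiguration is surfaced, not masked.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param history named vector \code{c(x =, y =, v =)}: the constant history
#'   value (components nonnegative).
#' @param t_end final time (days, > 0).
#' @param rel_tol,abs_tol relative and absolute solver tolerances.
#' @param max_step optional bound on the internal step size (days).
#' @param sample_dt spacing of the dense storage grid (days); the default
#'   resolves the fastest relevant time scales of the preset scenarios.
#' @return A \code{virotherapy_trajectory} object: the solution on the dense
#'   grid (as a tibble via \code{as_tibble()}), evaluable at any time in
#'   \eqn{[-\tau_{max}, t_{end}]} through \code{\link{trajectory_at}}.
#' @examples
#' p <- virotherapy_params(
#'   r0 = 0.7,
#'   transmission = data.frame(beta = 1e-3, tau = 0)
#' )
#' traj <- simulate_virotherapy(p, c(x = 127, y = 0, v = 30), t_end = 200)
#' tail(tibble::as_tibble(traj))
#' @export
simulate_virotherapy <- function(params, history, t_end,
                                 rel_tol = 1e-8, abs_tol = 1e-10,
                                 max_step = NULL, sample_dt = 0.25) {
  stopifnot(inherits(params, "virotherapy_params"))
  history <- as_state(history)
  if (any(history < 0))
    stop("history components must be nonnegative", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("`t_end` must be a single positive number", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)

  betas <- params$transmission$beta
  taus <- params$transmission$tau
  tau_max <- max(taus)
  beta <- sum(betas)
  r <- params$r; K <- params$K; rho <- params$rho
  delta <- params$delta; gamma <- params$gamma; b <- params$b
  pos <- which(taus > 0)

  times <- seq(0, t_end, by = sample_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  # force the first-generation breakpoints onto the mesh
  brk <- taus[taus > 0 & taus < t_end]
  times <- sort(unique(c(times, brk)))

  deriv <- function(t, y, parms) {
    x <- y[1]; yy <- y[2]; v <- y[3]
    infection <- if (length(pos) < length(betas)) betas[taus == 0][1] * x * v else 0
    for (i in pos) {
      if (t - taus[i] <= 0) {
        xd <- history[[1]]; vd <- history[[3]]
      } else {
        lag <- deSolve::lagvalue(t - taus[i], c(1, 3))
        xd <- lag[1]; vd <- lag[2]
      }
      infection <- infection + betas[i] * xd * vd
    }
    list(c(r * x * (1 - (x + yy) / K) - beta * x * v - rho * x * yy,
           infection - delta * yy,
           b * delta * yy - gamma * v - beta * x * v))
  }

  hmax <- if (is.null(max_step)) Inf else max_step
  sol <- if (length(pos) > 0L) {
    deSolve::dede(y = unname(history), times = times, func = deriv,
                  parms = NULL, rtol = rel_tol, atol = abs_tol, hmax = hmax,
                  control = list(mxhist = 1e5))
  } else {
    deSolve::ode(y = unname(history), times = times, func = deriv,
                 parms = NULL, rtol = rel_tol, atol = abs_tol, hmax = hmax)
  }
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed (solver istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  m <- unclass(sol)
  if (nrow(m) < length(times))
    stop("integration stopped early at t = ", max(m[, 1]), call. = FALSE)
  state <- m[, 2:4, drop = FALSE]
  if (any(!is.finite(state)) || max(abs(state)) > 1e6 * K)
    stop("blow-up: state norm exceeded 1e6 * K during integration",
         call. = FALSE)
  if (min(state) < -abs_tol)
    stop(sprintf(
      "negative state excursion (min = %.3e) beyond abs_tol; tighten tolerances",
      min(state)), call. = FALSE)

  interp <- lapply(1:3, function(j) stats::splinefun(m[, 1], m[, j + 1],
                                                     method = "fmm"))
  structure(
    list(params = params, history = history, t_end = t_end,
         tau_max = tau_max, times = m[, 1],
         data = tibble::tibble(t = m[, 1], x = state[, 1],
                               y = state[, 2], v = state[, 3]),
         interp = interp,
         rel_tol = rel_tol, abs_tol = abs_tol),
    class = "virotherapy_trajectory"
  )
}

#' @export
print.virotherapy_trajectory <- function(x, ...) {
  cat(sprintf("<virotherapy_trajectory> span [%g, %g], %d stored points\n",
              -x$tau_max, x$t_end, nrow(x$data)))
  terminal <- x$data[nrow(x$data), ]
  cat(sprintf("  terminal state: x = %.6g, y = %.6g, v = %.6g\n",
              terminal$x, terminal$y, terminal$v))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.virotherapy_trajectory <- function(x, ...) x$data

#' Evaluate a trajectory at arbitrary times
#'
#' Dense evaluation of the stored solution: on \eqn{[-\tau_{max}, 0]} the
#' (constant) history is returned; on \eqn{[0, t_{end}]} the solution is
#' interpolated from the dense storage grid. Times outside the span are an
#' error. Evaluation is deterministic: the same times always give bitwise
#' identical states.
#'
#' @param traj a \code{virotherapy_trajectory}.
#' @param times numeric vector of times within the span.
#' @return A tibble with columns \code{t}, \code{x}, \code{y}, \code{v}.
#' @export
trajectory_at <- function(traj, times) {
  stopifnot(inherits(traj, "virotherapy_trajectory"))
  if (any(times < -traj$tau_max - 1e-12) || any(times > traj$t_end + 1e-12))
    stop(sprintf("time out of trajectory span [%g, %g]",
                 -traj$tau_max, traj$t_end), call. = FALSE)
  past <- times < 0
  out <- matrix(NA_real_, length(times), 3)
  if (any(past))
    out[past, ] <- matrix(traj$history, sum(past), 3, byrow = TRUE)
  if (any(!past)) {
    tt <- times[!past]
    out[!past, ] <- cbind(traj$interp[[1]](tt), traj$interp[[2]](tt),
                          traj$interp[[3]](tt))
  }
  tibble::tibble(t = times, x = out[, 1], y = out[, 2], v = out[, 3])
}

#' Terminal state of a trajectory
#'
#' @param traj a \code{virotherapy_trajectory}.
#' @return Named vector \code{c(x, y, v)} at \code{t_end}.
#' @export
terminal_state <- function(traj) {
  stopifnot(inherits(traj, "virotherapy_trajectory"))
  last <- traj$data[nrow(traj$data), ]
  c(x = last$x, y = last$y, v = last$v)
}

#' Write a trajectory to CSV
#'
#' Plain CSV with header \code{t,x,y,v} on the requested grid (the dense
#' storage grid by default).
#'
#' @param traj a \code{virotherapy_trajectory}.
#' @param path output file path.
#' @param times optional sampling times (within the span).
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, times = NULL) {
  df <- if (is.null(times)) traj$data else trajectory_at(traj, times)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
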