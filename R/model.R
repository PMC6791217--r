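#' Model right-hand side
#'
#' Evaluates the time derivative of the delayed virotherapy system at the
#' current state, given the lagged states required by each transmission term.
#' Only the infected-cell gain term reads the past: each transmission term
#' contributes \eqn{\beta_i x(t-\tau_i) v(t-\tau_i)}. The loss terms use the
#' current state and the total rate \eqn{\beta}.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param state named numeric vector \code{c(x =, y =, v =)}: current state.
#' @param lagged matrix with one row per transmission term and columns
#'   \code{x}, \code{y}, \code{v}: the state at \code{t - tau_i}. The row for
#'   a \code{tau = 0} term must equal \code{state}. Defaults to the current
#'   state for every term (valid at steady state and for all-zero delays).
#' @return Named numeric derivative vector \code{c(x, y, v)}.
#' @export
model_rhs <- function(params, state,
                      lagged = matrix(rep(state, each = nrow(params$transmission)),
                                      ncol = 3,
                                      dimnames = list(NULL, c("x", "y", "v")))) {
  stopifnot(inherits(params, "virotherapy_params"))
  state <- as_state(state)
  if (!is.matrix(lagged) || nrow(lagged) != nrow(params$transmission) ||
      ncol(lagged) != 3L)
    stop("`lagged` must be a matrix with one (x, y, v) row per transmission term",
         call. = FALSE)
  beta <- beta_total(params)
  x <- state[["x"]]; y <- state[["y"]]; v <- state[["v"]]
  infection <- sum(params$transmission$beta * lagged[, 1] * lagged[, 3])
  c(x = params$r * x * (1 - (x + y) / params$K) - beta * x * v -
        params$rho * x * y,
    y = infection - params$delta * y,
    v = params$b * params$delta * y - params$gamma * v - beta * x * v)
}

as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 3L)
    stop("a state must be three numbers (x, y, v)", call. = FALSE)
  if (is.null(names(state)) || !all(c("x", "y", "v") %in% names(state)))
    names(state) <- c("x", "y", "v")
  state[c("x", "y", "v")]
}

#' Residual of the steady-state equations
#'
#' Max-norm of the right-hand side evaluated with every lagged state equal to
#' the point itself (delays are irrelevant at a steady state). Zero exactly
#' at an equilibrium.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param point candidate state \code{c(x =, y =, v =)}.
#' @return Nonnegative scalar.
#' @export
equilibrium_residual <- function(params, point) {
  point <- as_state(point)
  max(abs(model_rhs(params, point)))
}

#' Equilibria of the virotherapy model
#'
#' Returns the three candidate steady states: extinction \eqn{E_0 = (0,0,0)}
#' (complete tumor eradication), therapy failure \eqn{E_1 = (K, 0, 0)}
#' (tumor at carrying capacity, virus cleared), and — when \eqn{R_0 > 1} —
#' the endemic equilibrium
#' \deqn{x^* = \frac{\gamma}{\beta(b-1)}, \quad
#'       y^* = \frac{\gamma r (K b \beta - K\beta - \gamma)}
#'                  {\beta(b-1)[r\gamma + \delta K \beta (b-1) + \rho K \gamma]}, \quad
#'       v^* = \frac{\delta r (K b \beta - K\beta - \gamma)}
#'                  {\beta[r\gamma + \delta K \beta (b-1) + \rho K \gamma]}}
#' at which tumor cells and virus coexist. Each returned point is verified to
#' satisfy the steady-state equations to a residual below \code{1e-9}.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @return A tibble with one row per equilibrium and columns
#'   \code{equilibrium} (\code{"E0"}, \code{"E1"}, \code{"Estar"}),
#'   \code{x}, \code{y}, \code{v} and \code{residual}; the \code{"Estar"} row
#'   is absent when no positive equilibrium exists. The logical attribute
#'   \code{exists_endemic} flags its presence.
#' @examples
#' p <- virotherapy_params(
#'   r0 = 1.5,
#'   transmission = data.frame(beta = c(1e-5, 1e-4), tau = c(0, 7))
#' )
#' equilibria(p)
#' @export
equilibria <- function(params) {
  stopifnot(inherits(params, "virotherapy_params"))
  beta <- beta_total(params)
  r <- params$r; K <- params$K; rho <- params$rho
  delta <- params$delta; gamma <- params$gamma; b <- params$b

  rows <- list(
    tibble::tibble(equilibrium = "E0", x = 0, y = 0, v = 0),
    tibble::tibble(equilibrium = "E1", x = K, y = 0, v = 0)
  )
  # Positive equilibrium exists iff beta*K*(b-1) > gamma, i.e. R0 > 1.
  num <- K * b * beta - K * beta - gamma
  exists_endemic <- b > 1 && num > 0
  if (exists_endemic) {
    den <- r * gamma + delta * K * beta * (b - 1) + rho * K * gamma
    xs <- gamma / (beta * (b - 1))
    ys <- gamma * r * num / (beta * (b - 1) * den)
    vs <- delta * r * num / (beta * den)
    exists_endemic <- xs > 0 && ys > 0 && vs > 0
    if (exists_endemic)
      rows <- c(rows, list(tibble::tibble(equilibrium = "Estar",
                                          x = xs, y = ys, v = vs)))
  }
  out <- dplyr::bind_rows(rows)
  out$residual <- purrr::pmap_dbl(out[, c("x", "y", "v")], function(x, y, v)
    equilibrium_residual(params, c(x = x, y = y, v = v)))
  if (any(out$residual > 1e-9))
    stop("internal error: equilibrium residual exceeds 1e-9", call. = FALSE)
  attr(out, "exists_endemic") <- exists_endemic
  out
}

#' Endemic equilibrium as a state vector
#'
#' Convenience accessor for the positive equilibrium row of
#' \code{\link{equilibria}}.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @return Named vector \code{c(x, y, v)}.
#' @export
endemic_equilibrium <- function(params) {
  eq <- equilibria(params)
  row <- eq[eq$equilibrium == "Estar", ]
  if (nrow(row) == 0L)
    stop("no endemic equilibrium: R0 <= 1 for these parameters", call. = FALSE)
  c(x = row$x, y = row$y, v = row$v)
}
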