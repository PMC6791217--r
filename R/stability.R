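#' Spectrum at the therapy-failure equilibrium with zero delays
#'
#' Closed-form eigenvalues of the Jacobian at \eqn{E_1 = (K, 0, 0)} when all
#' delays vanish: \eqn{\lambda_1 = -r} and
#' \eqn{\lambda_{2,3} = (-(\gamma + \beta K + \delta) \mp \sqrt{\Delta})/2}
#' with \eqn{\Delta = (\gamma + \beta K - \delta)^2 + 4\beta K b \delta}.
#' \eqn{\lambda_3} changes sign exactly at \eqn{R_0 = 1}: the therapy-failure
#' state is locally stable when the virus cannot sustain itself.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @return A list of class \code{dfe_spectrum} with fields \code{lambda1},
#'   \code{lambda2}, \code{lambda3}, \code{Delta} and \code{r0}.
#' @export
dfe_spectrum <- function(params) {
  stopifnot(inherits(params, "virotherapy_params"))
  beta <- beta_total(params)
  bK <- beta * params$K
  g <- params$gamma; d <- params$delta
  Delta <- (g + bK - d)^2 + 4 * bK * params$b * d
  s <- g + bK + d
  structure(
    list(lambda1 = -params$r,
         lambda2 = (-s - sqrt(Delta)) / 2,
         lambda3 = (-s + sqrt(Delta)) / 2,
         Delta = Delta,
         r0 = reproduction_number(params)),
    class = "dfe_spectrum"
  )
}

#' Delay-robustness certificate for the therapy-failure equilibrium
#'
#' Tests whether the characteristic equation at \eqn{E_1} can acquire a
#' purely imaginary root for \emph{any} choice of delays. A crossing
#' frequency \eqn{\omega} would have to satisfy
#' \eqn{\omega^4 + a_1\omega^2 + a_2(\omega) + a_3 = 0} with
#' \eqn{a_1 = (\gamma + \beta K)^2 + \delta^2},
#' \eqn{a_2(\omega) = 2 (bK\delta)^2 \sum_{i<j} \beta_i\beta_j
#'   (1 - \cos\omega(\tau_i - \tau_j))} and
#' \eqn{a_3 = \delta^2 (\gamma + \beta K)^2 (1 - R_0^2)}.
#' Since \eqn{a_1 > 0} and \eqn{a_2 \ge 0} always, no such root exists when
#' \eqn{R_0 < 1} (so \eqn{a_3 > 0}); the local stability of \eqn{E_1} is then
#' independent of the delays. Positivity of \eqn{a_2} is confirmed on a
#' frequency grid, and the grid-based semantics are recorded in the
#' certificate.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param omega_grid frequencies at which \eqn{a_2(\omega)} is evaluated;
#'   the default is 10^4 points on \eqn{(0, 10\max(1,\sqrt{a_1})]}.
#' @return A list of class \code{dfe_robustness} with the coefficients, the
#'   grid minimum of \eqn{a_2}, and \code{certified} (TRUE iff \eqn{R_0 < 1}
#'   and all positivity checks hold).
#' @export
dfe_delay_robustness <- function(params, omega_grid = NULL) {
  stopifnot(inherits(params, "virotherapy_params"))
  beta <- beta_total(params)
  bK <- beta * params$K
  g <- params$gamma; d <- params$delta
  r0 <- reproduction_number(params)
  a1 <- (g + bK)^2 + d^2
  a3 <- d^2 * (g + bK)^2 * (1 - r0^2)
  if (is.null(omega_grid)) {
    omega_max <- 10 * max(1, sqrt(a1))
    omega_grid <- seq(omega_max / 1e4, omega_max, length.out = 1e4)
  }
  if (length(omega_grid) == 0L)
    stop("`omega_grid` must be nonempty", call. = FALSE)

  betas <- params$transmission$beta
  taus <- params$transmission$tau
  scale2 <- 2 * (params$b * params$K * d)^2
  a2 <- function(w) {
    acc <- 0
    n <- length(betas)
    if (n > 1L)
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        acc <- acc + betas[i] * betas[j] * (1 - cos(w * (taus[i] - taus[j])))
    scale2 * acc
  }
  a2_min <- min(vapply(omega_grid, a2, numeric(1)))
  structure(
    list(a1 = a1, a2_min = a2_min, a3 = a3, r0 = r0,
         certified = r0 < 1 && a1 > 0 && a3 > 0 && a2_min >= 0,
         semantics = "a2 positivity checked on a finite frequency grid",
         omega_range = range(omega_grid), n_grid = length(omega_grid)),
    class = "dfe_robustness"
  )
}

#' Characteristic coefficients at the endemic equilibrium
#'
#' The characteristic equation at \eqn{E^*} has the transcendental form
#' \deqn{\lambda^3 + A\lambda^2 + \tilde{B}\lambda + C +
#'       \sum_i \beta_i e^{-\lambda\tau_i} (D\lambda + E) = 0.}
#' The coefficients are obtained from the determinant expansion of the
#' delayed Jacobian at \eqn{E^*}: with \eqn{a = r x^*/K} and
#' \eqn{e_1 = \gamma + \beta x^*},
#' \deqn{A = a + \delta + e_1, \quad
#'       \tilde{B} = a(\delta + e_1) + \delta e_1 - \beta^2 x^* v^*, \quad
#'       C = a\,\delta\,e_1 - \delta\beta^2 x^* v^*,}
#' \deqn{D = (r/K + \rho) x^* v^* - b\delta x^*, \quad
#'       E = ((r/K + \rho)\gamma + b\delta\beta) x^* v^* - (r/K) b\delta x^{*2}.}
#' When the transmission list has exactly one positive delay
#' (\eqn{\beta_1, \tau_1}, plus optionally an instantaneous term
#' \eqn{\beta_0}), the constants of the imaginary-axis crossing polynomial
#' \eqn{\omega^6 + K_1\omega^4 + K_2\omega^2 + K_3 = 0} are also returned:
#' \eqn{K_1 = A^2 - 2(\tilde{B} + \beta_0 D)},
#' \eqn{K_2 = (\tilde{B} + \beta_0 D)^2 - 2A(C + \beta_0 E) - (\beta_1 D)^2},
#' \eqn{K_3 = (C + \beta_0 E)^2 - (\beta_1 E)^2}.
#'
#' @param params a \code{\link{virotherapy_params}} object with \eqn{R_0 > 1}.
#' @return A list of class \code{char_coefficients} with fields \code{A},
#'   \code{B_tilde}, \code{C}, \code{D}, \code{E}, \code{beta0} (rate of the
#'   instantaneous term, 0 if absent), \code{equilibrium}, and — for a single
#'   positive delay — \code{K1}, \code{K2}, \code{K3}.
#' @export
characteristic_coefficients <- function(params) {
  stopifnot(inherits(params, "virotherapy_params"))
  es <- endemic_equilibrium(params)
  beta <- beta_total(params)
  xs <- es[["x"]]; vs <- es[["v"]]
  r <- params$r; K <- params$K; rho <- params$rho
  delta <- params$delta; gamma <- params$gamma; b <- params$b

  a <- r * xs / K
  e1 <- gamma + beta * xs
  A <- a + delta + e1
  B_tilde <- a * (delta + e1) + delta * e1 - beta^2 * xs * vs
  C <- a * delta * e1 - delta * beta^2 * xs * vs
  D <- (r / K + rho) * xs * vs - b * delta * xs
  E <- ((r / K + rho) * gamma + b * delta * beta) * xs * vs -
    (r / K) * b * delta * xs^2

  taus <- params$transmission$tau
  betas <- params$transmission$beta
  beta0 <- if (any(taus == 0)) betas[taus == 0][1] else 0
  out <- list(A = A, B_tilde = B_tilde, C = C, D = D, E = E,
              beta0 = beta0, equilibrium = es)
  pos <- which(taus > 0)
  out$K1 <- A^2 - 2 * (B_tilde + beta0 * D)
  if (length(pos) == 1L) {
    beta1 <- betas[pos]
    out$K2 <- (B_tilde + beta0 * D)^2 - 2 * A * (C + beta0 * E) -
      (beta1 * D)^2
    out$K3 <- (C + beta0 * E)^2 - (beta1 * E)^2
  }
  structure(out, class = "char_coefficients")
}

#' Routh-Hurwitz stability of the endemic equilibrium at zero delay
#'
#' With all delays set to zero the characteristic equation collapses to the
#' cubic \eqn{\lambda^3 + b_1\lambda^2 + b_2\lambda + b_3 = 0} with
#' \eqn{b_1 = A}, \eqn{b_2 = \tilde{B} + \beta D},
#' \eqn{b_3 = C + \beta E} (\eqn{\beta} the total transmission rate).
#' The Routh-Hurwitz criterion places all roots in the open left half-plane
#' iff \eqn{b_1 > 0}, \eqn{b_2 > 0}, \eqn{b_3 > 0} and
#' \eqn{H_2 = b_1 b_2 - b_3 > 0}.
#'
#' @param params a \code{\link{virotherapy_params}} object with \eqn{R_0 > 1}.
#' @param marginal_tol quantities within this distance of zero yield the
#'   verdict \code{"marginal"} rather than a sign call.
#' @return A list of class \code{rh_report}: \code{b1}, \code{b2}, \code{b3},
#'   \code{H2} and \code{verdict} (\code{"stable"}, \code{"unstable"} or
#'   \code{"marginal"}).
#' @export
endemic_tau0_stability <- function(params, marginal_tol = 1e-9) {
  cf <- characteristic_coefficients(params)
  beta <- beta_total(params)
  b1 <- cf$A
  b2 <- cf$B_tilde + beta * cf$D
  b3 <- cf$C + beta * cf$E
  H2 <- b1 * b2 - b3
  q <- c(b1, b2, b3, H2)
  verdict <- if (any(abs(q) < marginal_tol)) "marginal"
  else if (all(q > 0)) "stable" else "unstable"
  structure(list(b1 = b1, b2 = b2, b3 = b3, H2 = H2, verdict = verdict),
            class = "rh_report")
}

#' Delay-independence condition at the endemic equilibrium
#'
#' A purely imaginary characteristic root at \eqn{E^*} must satisfy
#' \eqn{\omega^6 + K_1\omega^4 + K_2(\omega)\omega^2 + K_3(\omega) = 0},
#' where for a general transmission list the cross terms between distinct
#' delays make \eqn{K_2} and \eqn{K_3} frequency dependent:
#' with \eqn{S(\omega) = (\sum_{i\ge 1}\beta_i)^2 - 2\sum_{i<j}
#' \beta_i\beta_j (1 - \cos\omega(\tau_i - \tau_j))} over the delayed terms,
#' \eqn{K_2(\omega) = (\tilde{B}+\beta_0 D)^2 - 2A(C+\beta_0 E) -
#' D^2 S(\omega)} and \eqn{K_3(\omega) = (C+\beta_0 E)^2 - E^2 S(\omega)}.
#' If \eqn{K_1 > 0} and \eqn{K_2, K_3 > 0} for every frequency, no crossing
#' exists and the endemic equilibrium inherits its zero-delay stability for
#' all delays. Positivity is checked on a frequency grid (sufficient-check
#' semantics, recorded in the certificate). For a single positive delay the
#' \eqn{K_i} are constants and coincide with the values reported by
#' \code{\link{characteristic_coefficients}}.
#'
#' @param params a \code{\link{virotherapy_params}} object with \eqn{R_0 > 1}.
#' @param omega_grid frequencies for the positivity check; default 10^4
#'   points on \eqn{(0, 10\max(1, A, \sqrt{|K_1|})]}.
#' @return A list of class \code{endemic_delay_certificate}: \code{K1},
#'   \code{K2_min}, \code{K3_min}, the zero-delay verdict, and
#'   \code{certified}.
#' @export
endemic_delay_condition <- function(params, omega_grid = NULL) {
  cf <- characteristic_coefficients(params)
  if (is.null(omega_grid)) {
    omega_max <- 10 * max(1, cf$A, sqrt(abs(cf$K1)))
    omega_grid <- seq(omega_max / 1e4, omega_max, length.out = 1e4)
  }
  if (length(omega_grid) == 0L)
    stop("`omega_grid` must be nonempty", call. = FALSE)

  betas <- params$transmission$beta
  taus <- params$transmission$tau
  dl <- which(taus > 0)
  bsum <- sum(betas[dl])
  S <- vapply(omega_grid, function(w) {
    acc <- 0
    if (length(dl) > 1L)
      for (ii in seq_len(length(dl) - 1)) for (jj in (ii + 1):length(dl)) {
        i <- dl[ii]; j <- dl[jj]
        acc <- acc + betas[i] * betas[j] * (1 - cos(w * (taus[i] - taus[j])))
      }
    bsum^2 - 2 * acc
  }, numeric(1))
  P2 <- (cf$B_tilde + cf$beta0 * cf$D)^2 - 2 * cf$A * (cf$C + cf$beta0 * cf$E)
  P3 <- (cf$C + cf$beta0 * cf$E)^2
  K2w <- P2 - cf$D^2 * S
  K3w <- P3 - cf$E^2 * S
  tau0 <- endemic_tau0_stability(params)
  structure(
    list(K1 = cf$K1, K2_min = min(K2w), K3_min = min(K3w),
         tau0_verdict = tau0$verdict,
         certified = cf$K1 > 0 && min(K2w) > 0 && min(K3w) > 0 &&
           tau0$verdict == "stable",
         semantics = "K2, K3 positivity checked on a finite frequency grid",
         omega_range = range(omega_grid), n_grid = length(omega_grid)),
    class = "endemic_delay_certificate"
  )
}

transmission_factor <- function(params, lambda, delays_active = TRUE) {
  betas <- params$transmission$beta
  taus <- params$transmission$tau
  if (!delays_active) return(sum(betas) + 0i)
  sum(betas * exp(-lambda * taus))
}

#' Exact transcendental characteristic function
#'
#' Evaluates \eqn{\det(J(\lambda) - \lambda I)} at an equilibrium, with the
#' delayed Jacobian entries carrying their \eqn{e^{-\lambda\tau_i}} factors
#' (or frozen at \eqn{\tau_i = 0} when \code{delays_active = FALSE}). This
#' is the ground truth against which the closed-form coefficient expansions
#' are validated, and the function whose roots are tracked across the Hopf
#' crossing.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @param lambda complex (or real) evaluation point.
#' @param which equilibrium: \code{"E1"} (therapy failure) or \code{"Estar"}.
#' @param delays_active if FALSE the delay factors are replaced by 1.
#' @return Complex scalar \eqn{\det(J(\lambda) - \lambda I)}.
#' @export
characteristic_value <- function(params, lambda, which = c("Estar", "E1"),
                                 delays_active = TRUE) {
  stopifnot(inherits(params, "virotherapy_params"))
  which <- match.arg(which)
  point <- if (which == "E1") c(x = params$K, y = 0, v = 0)
  else endemic_equilibrium(params)
  lambda <- as.complex(lambda)
  beta <- beta_total(params)
  r <- params$r; K <- params$K; rho <- params$rho
  delta <- params$delta; gamma <- params$gamma; b <- params$b
  x <- point[["x"]]; y <- point[["y"]]; v <- point[["v"]]
  s <- transmission_factor(params, lambda, delays_active)

  J11 <- r * (1 - (2 * x + y) / K) - beta * v - rho * y
  J12 <- -r * x / K - rho * x
  J13 <- -beta * x
  J21 <- s * v
  J22 <- -delta + 0i
  J23 <- s * x
  J31 <- -beta * v
  J32 <- b * delta
  J33 <- -gamma - beta * x

  m11 <- J11 - lambda; m22 <- J22 - lambda; m33 <- J33 - lambda
  m11 * (m22 * m33 - J23 * J32) -
    J12 * (J21 * m33 - J23 * J31) +
    J13 * (J21 * J32 - m22 * J31)
}

#' Coefficient-form characteristic polynomial at the endemic equilibrium
#'
#' Evaluates \eqn{P(\lambda) = \lambda^3 + A\lambda^2 + \tilde{B}\lambda + C
#' + \sum_i \beta_i e^{-\lambda\tau_i}(D\lambda + E)} from the closed-form
#' coefficients. Related to the determinant by
#' \eqn{P(\lambda) = -\det(J(\lambda) - \lambda I)}; the agreement of the two
#' routes at arbitrary complex \eqn{\lambda} validates the coefficient
#' derivation.
#'
#' @param params a \code{\link{virotherapy_params}} object with \eqn{R_0 > 1}.
#' @param lambda complex evaluation point.
#' @param delays_active if FALSE the delay factors are replaced by 1.
#' @param coeffs optional precomputed \code{\link{characteristic_coefficients}}.
#' @return Complex scalar \eqn{P(\lambda)}.
#' @export
characteristic_poly_value <- function(params, lambda, delays_active = TRUE,
                                      coeffs = NULL) {
  cf <- if (is.null(coeffs)) characteristic_coefficients(params) else coeffs
  lambda <- as.complex(lambda)
  s <- transmission_factor(params, lambda, delays_active)
  lambda^3 + cf$A * lambda^2 + cf$B_tilde * lambda + cf$C +
    s * (cf$D * lambda + cf$E)
}
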