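single_delay_info <- function(params) {
  taus <- params$transmission$tau
  pos <- which(taus > 0)
  if (length(pos) != 1L)
    stop("Hopf analysis requires exactly one positive-delay transmission term",
         call. = FALSE)
  list(beta1 = params$transmission$beta[pos], tau1 = taus[pos])
}

#' Hopf crossing frequency for the single-delay case
#'
#' A purely imaginary root \eqn{i\omega} of the endemic characteristic
#' equation with one positive delay must satisfy
#' \eqn{\omega^6 + K_1\omega^4 + K_2\omega^2 + K_3 = 0}. Substituting
#' \eqn{u = \omega^2} gives a real cubic whose positive real roots are the
#' candidate crossing frequencies squared; \eqn{\omega_0} is taken as the
#' square root of the largest. When \eqn{K_3 < 0} at least one positive root
#' is guaranteed (the cubic is negative at the origin).
#'
#' @param params a \code{\link{virotherapy_params}} object with exactly one
#'   positive-delay transmission term and \eqn{R_0 > 1}.
#' @return A list with \code{omega0} (NA when no crossing exists),
#'   \code{crossing_frequencies} (all positive-root frequencies, decreasing),
#'   \code{u_roots}, and the cubic coefficients \code{K1}, \code{K2},
#'   \code{K3}.
#' @export
crossing_frequency <- function(params) {
  single_delay_info(params)
  cf <- characteristic_coefficients(params)
  roots <- polyroot(c(cf$K3, cf$K2, cf$K1, 1))
  re <- Re(roots)
  real_pos <- re[abs(Im(roots)) < 1e-8 * pmax(1, abs(re)) & re > 0]
  freqs <- sort(sqrt(real_pos), decreasing = TRUE)
  list(omega0 = if (length(freqs)) freqs[1] else NA_real_,
       crossing_frequencies = freqs,
       u_roots = roots, K1 = cf$K1, K2 = cf$K2, K3 = cf$K3)
}

crossing_angle <- function(cf, beta1, omega) {
  # solve the real/imaginary crossing system for cos and sin at frequency omega
  Rp <- -cf$A * omega^2 + cf$C + cf$beta0 * cf$E
  Ip <- -omega^3 + (cf$B_tilde + cf$beta0 * cf$D) * omega
  den <- beta1 * (cf$E^2 + cf$D^2 * omega^2)
  cosv <- -(cf$E * Rp + cf$D * omega * Ip) / den
  sinv <- -(cf$D * omega * Rp - cf$E * Ip) / den
  list(cos = cosv, sin = sinv)
}

#' Hopf bifurcation analysis: critical delay and transversality
#'
#' For the single-positive-delay scenario, computes the crossing frequency
#' \eqn{\omega_0}, recovers \eqn{\cos\omega_0\tau} and \eqn{\sin\omega_0\tau}
#' from the linear real/imaginary crossing system (the two-argument angle
#' removes the quadrant ambiguity of an arccos alone), enumerates the branch
#' delays \eqn{\tau_j = (\theta + 2\pi j)/\omega_0} and returns the smallest
#' positive one as the critical delay \eqn{\tau^*}. Below \eqn{\tau^*} the
#' endemic equilibrium is locally asymptotically stable; at \eqn{\tau^*} a
#' conjugate eigenvalue pair reaches the imaginary axis and, when the
#' transversality condition holds, crosses it, producing a Hopf bifurcation
#' and sustained oscillations for \eqn{\tau > \tau^*}.
#'
#' The transversality sign is computed as \eqn{\mathrm{sign}\,h'(\omega_0^2)}
#' for \eqn{h(u) = u^3 + K_1 u^2 + K_2 u + K_3} and, unless disabled,
#' cross-validated by numerically continuing the characteristic root across
#' \eqn{\tau^*}: the tracked real part must change sign accordingly, and a
#' disagreement aborts.
#'
#' @param params a \code{\link{virotherapy_params}} object with exactly one
#'   positive-delay transmission term and \eqn{R_0 > 1}.
#' @param n_branches number of branch delays to report.
#' @param validate run the root-continuation cross-check (and the
#'   \eqn{\cos^2+\sin^2=1} and characteristic-value residual checks).
#' @return An object of class \code{hopf_result} with fields \code{omega0},
#'   \code{tau_star}, \code{branch_delays}, \code{cos_omega_tau},
#'   \code{sin_omega_tau}, \code{transversality_sign}, \code{k3_negative},
#'   \code{crossing_frequencies}, \code{char_residual}.
#' @examples
#' p <- virotherapy_params(
#'   r0 = 1.5,
#'   transmission = data.frame(beta = c(1e-5, 1e-4), tau = c(0, 7))
#' )
#' hopf_analysis(p)
#' @export
hopf_analysis <- function(params, n_branches = 5, validate = TRUE) {
  sd <- single_delay_info(params)
  cf <- characteristic_coefficients(params)
  freq <- crossing_frequency(params)
  if (is.na(freq$omega0)) {
    return(structure(
      list(omega0 = NA_real_, tau_star = NA_real_,
           branch_delays = numeric(0), transversality_sign = NA_integer_,
           k3_negative = cf$K3 < 0, crossing_frequencies = numeric(0),
           K1 = cf$K1, K2 = cf$K2, K3 = cf$K3),
      class = "hopf_result"))
  }
  omega0 <- freq$omega0
  ang <- crossing_angle(cf, sd$beta1, omega0)
  if (abs(ang$cos) > 1 + 1e-9)
    stop("inconsistent characteristic coefficients: |cos(omega0 tau)| > 1",
         call. = FALSE)
  unit_residual <- abs(ang$cos^2 + ang$sin^2 - 1)
  if (validate && unit_residual > 1e-6)
    stop("crossing system residual cos^2 + sin^2 - 1 = ",
         format(unit_residual), " exceeds 1e-6", call. = FALSE)
  theta <- atan2(ang$sin, ang$cos) %% (2 * pi)
  branch <- (theta + 2 * pi * (0:(n_branches - 1))) / omega0
  branch <- branch[branch > 0]
  tau_star <- min(branch)

  # delays of the principal branch for every crossing frequency
  all_delays <- vapply(freq$crossing_frequencies, function(w) {
    a <- crossing_angle(cf, sd$beta1, w)
    (atan2(a$sin, a$cos) %% (2 * pi)) / w
  }, numeric(1))

  h_deriv <- 3 * omega0^4 + 2 * freq$K1 * omega0^2 + freq$K2
  scale <- max(abs(c(freq$K1, freq$K2, freq$K3, 1)))
  sgn <- if (abs(h_deriv) < 1e-9 * scale) 0L else as.integer(sign(h_deriv))

  char_residual <- Mod(hopf_char_value(cf, sd$beta1,
                                       complex(imaginary = omega0), tau_star))
  res <- structure(
    list(omega0 = omega0, tau_star = tau_star, branch_delays = branch,
         cos_omega_tau = ang$cos, sin_omega_tau = ang$sin,
         transversality_sign = sgn, k3_negative = freq$K3 < 0,
         crossing_frequencies = freq$crossing_frequencies,
         crossing_delays = all_delays,
         K1 = freq$K1, K2 = freq$K2, K3 = freq$K3,
         char_residual = char_residual, degenerate = sgn == 0L),
    class = "hopf_result")

  if (validate && sgn != 0L) {
    track <- track_crossing_root(params, res, offset = 0.5)
    agree <- (sgn == 1L && track$re_below < 0 && track$re_above > 0) ||
      (sgn == -1L && track$re_below > 0 && track$re_above < 0)
    if (!agree)
      stop(sprintf(paste0(
        "transversality disagreement: h'(omega0^2) gives sign %d but the ",
        "tracked root has Re = %.3e below and %.3e above tau*"),
        sgn, track$re_below, track$re_above), call. = FALSE)
    res$root_track <- track
  }
  res
}

#' @export
print.hopf_result <- function(x, ...) {
  cat("<hopf_result>\n")
  if (is.na(x$omega0)) {
    cat("  no imaginary-axis crossing (all cubic roots nonpositive)\n")
  } else {
    cat(sprintf("  omega0 = %.6g rad/day, tau* = %.6g days\n",
                x$omega0, x$tau_star))
    cat(sprintf("  transversality sign = %+d, K3 %s 0\n",
                x$transversality_sign, if (x$k3_negative) "<" else ">="))
  }
  invisible(x)
}

# characteristic polynomial with the positive delay set explicitly
hopf_char_value <- function(cf, beta1, lambda, tau1) {
  lambda^3 + cf$A * lambda^2 + cf$B_tilde * lambda + cf$C +
    (cf$beta0 + beta1 * exp(-lambda * tau1)) * (cf$D * lambda + cf$E)
}

hopf_char_dlambda <- function(cf, beta1, lambda, tau1) {
  3 * lambda^2 + 2 * cf$A * lambda + cf$B_tilde + cf$beta0 * cf$D +
    beta1 * exp(-lambda * tau1) *
    (cf$D - tau1 * (cf$D * lambda + cf$E))
}

newton_char_root <- function(cf, beta1, lambda0, tau1, tol = 1e-12,
                             max_iter = 60) {
  lambda <- lambda0
  for (k in seq_len(max_iter)) {
    f <- hopf_char_value(cf, beta1, lambda, tau1)
    step <- f / hopf_char_dlambda(cf, beta1, lambda, tau1)
    lambda <- lambda - step
    if (Mod(step) < tol * max(1, Mod(lambda))) return(lambda)
  }
  warning("characteristic-root Newton iteration did not fully converge")
  lambda
}

#' Track the crossing characteristic root across the critical delay
#'
#' Continues the conjugate characteristic root that sits at
#' \eqn{\lambda = i\omega_0} when \eqn{\tau = \tau^*} to delays on either
#' side of \eqn{\tau^*} by stepwise Newton iteration on the exact
#' transcendental characteristic function. The sign of the tracked real part
#' on each side is the model-agnostic ground truth for transversality.
#'
#' @param params a \code{\link{virotherapy_params}} object (single positive
#'   delay, \eqn{R_0 > 1}).
#' @param result a \code{\link{hopf_analysis}} result with a crossing.
#' @param offset distance from \eqn{\tau^*} at which the real part is
#'   reported (days).
#' @param n_steps continuation steps on each side.
#' @return List with \code{re_below}, \code{re_above} (real parts at
#'   \eqn{\tau^* \mp} \code{offset}) and the tracked \code{path} tibble.
#' @export
track_crossing_root <- function(params, result, offset = 0.5, n_steps = 20) {
  sd <- single_delay_info(params)
  cf <- characteristic_coefficients(params)
  if (is.na(result$omega0)) stop("no crossing to track", call. = FALSE)
  tau_star <- result$tau_star
  path <- list()
  for (dir in c(-1, 1)) {
    lambda <- complex(imaginary = result$omega0)
    taus <- tau_star + dir * seq(0, offset, length.out = n_steps + 1)[-1]
    for (tau in taus)
      lambda <- newton_char_root(cf, sd$beta1, lambda, tau)
    path[[if (dir < 0) "below" else "above"]] <-
      tibble::tibble(tau = taus[length(taus)], re = Re(lambda), im = Im(lambda))
  }
  list(re_below = path$below$re, re_above = path$above$re,
       path = dplyr::bind_rows(below = path$below, above = path$above,
                               .id = "side"))
}

#' Transversality of the Hopf crossing
#'
#' Returns the sign of \eqn{h'(\omega_0^2)} for the crossing polynomial
#' \eqn{h(u) = u^3 + K_1 u^2 + K_2 u + K_3}, cross-validated against
#' numerical continuation of the characteristic root (the real part of the
#' tracked root must change sign across \eqn{\tau^*} consistently; a
#' disagreement aborts). A repeated root of \eqn{h} at \eqn{\omega_0^2}
#' yields 0 (degenerate crossing).
#'
#' @param params a \code{\link{virotherapy_params}} object (single positive
#'   delay, \eqn{R_0 > 1}).
#' @param result optional precomputed \code{\link{hopf_analysis}} result.
#' @return Integer sign: +1 (roots cross left to right as \eqn{\tau}
#'   increases), -1, or 0 (degenerate).
#' @export
transversality <- function(params, result = NULL) {
  if (is.null(result)) result <- hopf_analysis(params, validate = TRUE)
  if (is.na(result$omega0))
    stop("no crossing frequency: transversality undefined", call. = FALSE)
  result$transversality_sign
}
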