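#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Hopf analysis result
#'
#' One row per branch delay at the principal crossing frequency.
#'
#' @param x a \code{hopf_result}.
#' @param ... unused.
#' @return Tibble with columns \code{branch}, \code{tau}, \code{omega0}.
#' @export
tidy.hopf_result <- function(x, ...) {
  tibble::tibble(branch = seq_along(x$branch_delays) - 1L,
                 tau = x$branch_delays,
                 omega0 = rep(x$omega0, length(x$branch_delays)))
}

#' Glance at a Hopf analysis result
#'
#' @param x a \code{hopf_result}.
#' @param ... unused.
#' @return One-row tibble: \code{omega0}, \code{tau_star},
#'   \code{transversality_sign}, \code{k3_negative}, \code{K1}, \code{K2},
#'   \code{K3}, \code{char_residual}.
#' @export
glance.hopf_result <- function(x, ...) {
  tibble::tibble(omega0 = x$omega0, tau_star = x$tau_star,
                 transversality_sign = x$transversality_sign,
                 k3_negative = x$k3_negative,
                 K1 = x$K1, K2 = x$K2 %||% NA_real_, K3 = x$K3 %||% NA_real_,
                 char_residual = x$char_residual %||% NA_real_)
}

#' Tidy a zero-delay Routh-Hurwitz report
#'
#' @param x an \code{rh_report}.
#' @param ... unused.
#' @return Tibble with one row per Routh-Hurwitz quantity.
#' @export
tidy.rh_report <- function(x, ...) {
  tibble::tibble(quantity = c("b1", "b2", "b3", "H2"),
                 value = c(x$b1, x$b2, x$b3, x$H2))
}

#' @rdname tidy.rh_report
#' @export
glance.rh_report <- function(x, ...) {
  tibble::tibble(b1 = x$b1, b2 = x$b2, b3 = x$b3, H2 = x$H2,
                 verdict = x$verdict)
}

#' Tidy the zero-delay spectrum at the therapy-failure equilibrium
#'
#' @param x a \code{dfe_spectrum}.
#' @param ... unused.
#' @return Tibble with one row per eigenvalue.
#' @export
tidy.dfe_spectrum <- function(x, ...) {
  tibble::tibble(eigenvalue = c("lambda1", "lambda2", "lambda3"),
                 value = c(x$lambda1, x$lambda2, x$lambda3))
}

#' Glance at a scenario summary
#'
#' @param x a \code{scenario_summary}.
#' @param ... unused.
#' @return One-row tibble with the terminal state, convergence target,
#'   eradication time and tumor-load extrema.
#' @export
glance.scenario_summary <- function(x, ...) {
  tibble::tibble(x_end = x$terminal_state[["x"]],
                 y_end = x$terminal_state[["y"]],
                 v_end = x$terminal_state[["v"]],
                 converged_to = x$converged_to,
                 eradication_time = x$eradication_time,
                 load_min = x$tumor_load_extrema[["min"]],
                 load_max = x$tumor_load_extrema[["max"]],
                 r0 = x$r0)
}
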