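# Local maxima/minima on a sampled signal, with parabolic refinement of the
# peak location and value (the sampling grid alone limits period estimates).
find_extrema <- function(t, x) {
  d <- diff(sign(diff(x)))
  eval_parab <- function(i) {
    t0 <- t[i - 1]; t1 <- t[i]; t2 <- t[i + 1]
    y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
    denom <- (t0 - t1) * (t0 - t2) * (t1 - t2)
    a <- (t2 * (y1 - y0) + t1 * (y0 - y2) + t0 * (y2 - y1)) / denom
    b <- (t2^2 * (y0 - y1) + t1^2 * (y2 - y0) + t0^2 * (y1 - y2)) / denom
    cc <- y1 - a * t1^2 - b * t1
    if (a == 0) return(c(t1, y1))
    tv <- -b / (2 * a)
    if (tv < t0 || tv > t2) return(c(t1, y1))
    c(tv, a * tv^2 + b * tv + cc)
  }
  collect <- function(idx) {
    if (!length(idx)) return(tibble::tibble(t = numeric(0), value = numeric(0)))
    m <- t(vapply(idx, eval_parab, numeric(2)))
    tibble::tibble(t = m[, 1], value = m[, 2])
  }
  list(peaks = collect(which(d == -2) + 1L),
       troughs = collect(which(d == 2) + 1L))
}

#' Amplitude and period of an oscillating trajectory component
#'
#' Peak detection on a densely sampled component, with parabolic refinement
#' of extremum locations. The amplitude is the mean peak-to-trough excursion
#' over the last three full cycles; the period is the mean peak-to-peak
#' spacing. Both are \code{NA} when fewer than two peaks are found.
#'
#' @param traj a \code{virotherapy_trajectory}, or a data frame with a
#'   \code{t} column and the requested component column.
#' @param component which component to analyse: \code{"x"}, \code{"y"} or
#'   \code{"v"}.
#' @param window time interval \code{c(from, to)} to analyse (default: the
#'   whole nonnegative span).
#' @return List with \code{amplitude}, \code{period}, \code{n_peaks} and
#'   \code{peak_times}.
#' @export
oscillation_metrics <- function(traj, component = "x", window = NULL) {
  df <- if (inherits(traj, "virotherapy_trajectory")) traj$data
  else tibble::as_tibble(traj)
  stopifnot(component %in% names(df), "t" %in% names(df))
  if (!is.null(window)) {
    if (inherits(traj, "virotherapy_trajectory") &&
        (window[1] < -traj$tau_max || window[2] > traj$t_end))
      stop("window outside trajectory span", call. = FALSE)
    df <- df[df$t >= window[1] & df$t <= window[2], ]
  }
  ex <- find_extrema(df$t, df[[component]])
  n_peaks <- nrow(ex$peaks)
  if (n_peaks < 2L)
    return(list(amplitude = NA_real_, period = NA_real_,
                n_peaks = n_peaks, peak_times = ex$peaks$t))
  period <- mean(diff(ex$peaks$t))
  # peak-to-following-trough amplitudes, last 3 full cycles
  amps <- purrr::map_dbl(seq_len(n_peaks), function(i) {
    nxt <- ex$troughs$t > ex$peaks$t[i]
    if (!any(nxt)) return(NA_real_)
    ex$peaks$value[i] - ex$troughs$value[which(nxt)[1]]
  })
  amps <- amps[!is.na(amps)]
  amplitude <- if (length(amps)) mean(utils::tail(amps, 3)) else NA_real_
  list(amplitude = amplitude, period = period,
       n_peaks = n_peaks, peak_times = ex$peaks$t)
}

with_positive_delay <- function(params, tau) {
  trans <- params$transmission
  if (tau == 0) {
    trans <- tibble::tibble(beta = sum(trans$beta), tau = 0)
  } else {
    pos <- which(trans$tau > 0)
    if (length(pos) != 1L)
      stop("delay classification requires a single positive-delay term",
           call. = FALSE)
    trans$tau[pos] <- tau
  }
  virotherapy_params(r = params$r, K = params$K, rho = params$rho,
                     delta = params$delta, gamma = params$gamma,
                     b = params$b, transmission = trans)
}

#' Classify the dynamics on either side of the critical delay
#'
#' Integrates from a small deterministic perturbation of the endemic
#' equilibrium (componentwise \code{1 + perturbation}) with the positive
#' delay set to \code{tau}, discards the initial transient (first 20\% of
#' the horizon) and inspects the peak-to-trough amplitudes of the
#' uninfected-cell component about \eqn{x^*}:
#' \itemize{
#' \item \code{"damped"}: amplitudes decay monotonically by at least 1\% per
#'   cycle, or the oscillation has died out and the trajectory has contracted
#'   toward \eqn{E^*} (late deviation below a tenth of the early deviation);
#' \item \code{"sustained"}: the last few amplitudes agree within 5\%;
#' \item \code{"growing-then-bounded"}: amplitudes still growing at the end
#'   of the horizon;
#' \item \code{"inconclusive"}: fewer than 4 peaks and no clear contraction.
#' }
#'
#' @param params a \code{\link{virotherapy_params}} object with a single
#'   positive-delay term and \eqn{R_0 > 1}.
#' @param tau delay value to classify at (days); 0 collapses the system to
#'   its undelayed limit.
#' @param t_end integration horizon (days).
#' @param perturbation relative perturbation off \eqn{E^*} (deterministic).
#' @param rel_tol,abs_tol solver tolerances.
#' @return A list of class \code{delay_classification}: \code{classification},
#'   \code{amplitude}, \code{period}, \code{n_peaks}, \code{tau}.
#' @export
classify_delay <- function(params, tau, t_end = 3000, perturbation = 1e-2,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  p <- with_positive_delay(params, tau)
  es <- endemic_equilibrium(p)
  traj <- simulate_virotherapy(p, es * (1 + perturbation), t_end = t_end,
                               rel_tol = rel_tol, abs_tol = abs_tol)
  df <- traj$data[traj$data$t >= 0.2 * t_end, ]
  dev <- abs(df$x - es[["x"]])
  ex <- find_extrema(df$t, df$x)
  metrics <- oscillation_metrics(traj, "x", window = c(0.2 * t_end, t_end))

  amps <- purrr::map_dbl(seq_len(nrow(ex$peaks)), function(i) {
    nxt <- ex$troughs$t > ex$peaks$t[i]
    if (!any(nxt)) return(NA_real_)
    ex$peaks$value[i] - ex$troughs$value[which(nxt)[1]]
  })
  amps <- amps[!is.na(amps) & amps > 0]
  n <- length(amps)

  cls <- if (n < 4L) {
    n10 <- max(2L, ceiling(nrow(df) * 0.1))
    early <- max(dev[seq_len(n10)])
    late <- max(dev[seq(nrow(df) - n10 + 1, nrow(df))])
    if (late <= 0.1 * early || late < 1e-6 * p$K) "damped" else "inconclusive"
  } else {
    ratio <- amps[-1] / amps[-n]
    last <- utils::tail(amps, 5)
    if (all(ratio <= 0.99)) "damped"
    else if (max(last) / min(last) - 1 <= 0.05) "sustained"
    else "growing-then-bounded"
  }
  structure(list(classification = cls, amplitude = metrics$amplitude,
                 period = metrics$period, n_peaks = metrics$n_peaks,
                 tau = tau),
            class = "delay_classification")
}

#' @export
print.delay_classification <- function(x, ...) {
  cat(sprintf("<delay_classification> tau = %g: %s", x$tau, x$classification))
  if (!is.na(x$period)) cat(sprintf(" (period %.4g d)", x$period))
  cat("\n")
  invisible(x)
}

#' Classify a grid of delays
#'
#' Runs \code{\link{classify_delay}} for each delay and collects the results.
#'
#' @param params single-positive-delay parameter set with \eqn{R_0 > 1}.
#' @param taus numeric vector of delays (days).
#' @param ... passed to \code{\link{classify_delay}}.
#' @return Tibble with columns \code{tau}, \code{classification},
#'   \code{amplitude}, \code{period}.
#' @export
delay_scan <- function(params, taus, ...) {
  res <- purrr::map(taus, function(tau) {
    cl <- classify_delay(params, tau, ...)
    tibble::tibble(tau = tau, classification = cl$classification,
                   amplitude = cl$amplitude, period = cl$period)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("delay_scan", class(out))
  out
}

#' Locate the damped-to-sustained transition delay
#'
#' Bisection on the boundary of the \code{"damped"} classification between a
#' delay known to damp and one known not to. Near the Hopf point the
#' simulated transition should bracket the analytic critical delay.
#'
#' @param params single-positive-delay parameter set with \eqn{R_0 > 1}.
#' @param lower delay classified as damped.
#' @param upper delay classified as not damped.
#' @param tol bisection width at which to stop (days).
#' @param ... passed to \code{\link{classify_delay}}.
#' @return List with the bracketing interval \code{c(lower, upper)} and the
#'   midpoint estimate \code{transition}.
#' @export
find_hopf_transition <- function(params, lower, upper, tol = 0.1, ...) {
  cl_lo <- classify_delay(params, lower, ...)$classification
  cl_hi <- classify_delay(params, upper, ...)$classification
  if (cl_lo != "damped" || cl_hi == "damped")
    stop("bracket does not straddle the damped boundary (lower: ", cl_lo,
         ", upper: ", cl_hi, ")", call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (classify_delay(params, mid, ...)$classification == "damped")
      lower <- mid else upper <- mid
  }
  list(lower = lower, upper = upper, transition = (lower + upper) / 2)
}
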