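#' Construct a virotherapy parameter set
#'
#' Bundles the rate constants of the multi-delay virotherapy model together
#' with its transmission spectrum. The model tracks uninfected tumor cells
#' \eqn{x}, infected tumor cells \eqn{y} and free virus \eqn{v} (all in units
#' of \eqn{10^6} cells / virions):
#' \deqn{x' = r x (1 - (x+y)/K) - \beta x v - \rho x y}
#' \deqn{y' = \sum_i \beta_i x(t-\tau_i) v(t-\tau_i) - \delta y}
#' \deqn{v' = b \delta y - \gamma v - \beta x v}
#' where \eqn{\beta = \sum_i \beta_i} is the total infection rate over all
#' transmission terms, each \eqn{(\beta_i, \tau_i)} pair representing one
#' stage of the viral lytic cycle with its completion delay.
#'
#' The burst size \code{b} may be given directly, or indirectly through a
#' target basic reproduction number \code{r0}, in which case \code{b} is
#' solved from \eqn{R_0 = \beta K b / (\beta K + \gamma)}.
#'
#' @param r logistic growth rate of uninfected tumor cells (per day).
#' @param K carrying capacity / maximal tumor size (10^6 cells).
#' @param rho cell-to-cell fusion (syncytium formation) rate constant
#'   (per (10^6 cells) day).
#' @param delta infected-cell death rate (per day).
#' @param gamma free-virus clearance rate (per day); zero is allowed.
#' @param b burst size: new virions released per lysed cell (dimensionless).
#'   Exactly one of \code{b} and \code{r0} must be supplied.
#' @param r0 target basic reproduction number used to solve for \code{b}.
#' @param transmission data frame with columns \code{beta} and \code{tau}:
#'   one row per transmission term, \code{tau} strictly increasing, at most
#'   one row with \code{tau = 0}.
#'
#' @return An object of class \code{virotherapy_params}: a list with fields
#'   \code{r}, \code{K}, \code{rho}, \code{delta}, \code{gamma}, \code{b}
#'   and \code{transmission} (a tibble).
#' @examples
#' p <- virotherapy_params(
#'   r0 = 1.5,
#'   transmission = data.frame(beta = c(1e-5, 1e-4), tau = c(0, 7))
#' )
#' reproduction_number(p)
#' @export
virotherapy_params <- function(r = 0.206, K = 2139, rho = 0.2145,
                               delta = 0.5115, gamma = 0.001,
                               b = NULL, r0 = NULL,
                               transmission) {
  stopifnot(is.data.frame(transmission),
            all(c("beta", "tau") %in% names(transmission)))
  trans <- tibble::as_tibble(transmission[, c("beta", "tau")])
  validate_transmission(trans)
  for (nm in c("r", "K", "rho", "delta")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("`gamma` must be a single nonnegative number", call. = FALSE)
  if (is.null(b) == is.null(r0))
    stop("supply exactly one of `b` and `r0`", call. = FALSE)

  p <- structure(
    list(r = r, K = K, rho = rho, delta = delta, gamma = gamma,
         b = NA_real_, transmission = trans),
    class = "virotherapy_params"
  )
  p$b <- if (is.null(b)) burst_size_for_r0(p, r0) else b
  if (!is.finite(p$b) || p$b <= 0)
    stop("`b` must be positive", call. = FALSE)
  p
}

validate_transmission <- function(trans) {
  if (nrow(trans) == 0L) stop("transmission list must be nonempty", call. = FALSE)
  if (any(!is.finite(trans$beta)) || any(trans$beta < 0))
    stop("all `beta` values must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(trans$tau)) || any(trans$tau < 0))
    stop("all `tau` values must be finite and nonnegative", call. = FALSE)
  if (nrow(trans) > 1L && any(diff(trans$tau) <= 0))
    stop("`tau` values must be strictly increasing", call. = FALSE)
  if (sum(trans$tau == 0) > 1L)
    stop("at most one transmission term may have tau = 0", call. = FALSE)
  if (sum(trans$beta) <= 0)
    stop("total transmission rate must be positive", call. = FALSE)
  invisible(trans)
}

#' @export
print.virotherapy_params <- function(x, ...) {
  cat("<virotherapy_params>\n")
  cat(sprintf("  r = %g, K = %g, rho = %g, delta = %g, b = %g, gamma = %g\n",
              x$r, x$K, x$rho, x$delta, x$b, x$gamma))
  cat(sprintf("  beta_total = %g over %d transmission term(s), R0 = %.6g\n",
              beta_total(x), nrow(x$transmission), reproduction_number(x)))
  invisible(x)
}

#' Total infection rate
#'
#' Sum of the per-stage infection rates \eqn{\beta = \sum_i \beta_i},
#' including any instantaneous (\eqn{\tau = 0}) term. This total drives the
#' loss terms \eqn{\beta x v} in the uninfected-cell and virus equations and
#' enters the basic reproduction number.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @return Total rate (per (10^6 virions) day).
#' @export
beta_total <- function(params) {
  stopifnot(inherits(params, "virotherapy_params"))
  sum(params$transmission$beta)
}

#' Basic reproduction number
#'
#' \eqn{R_0 = \beta K b / (\beta K + \gamma)}: the expected number of new
#' virions produced by one virion introduced into a fully uninfected tumor
#' at carrying capacity. The therapy-failure equilibrium is globally stable
#' when \eqn{R_0 < 1}; a positive (endemic) equilibrium exists iff
#' \eqn{R_0 > 1}.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @return Dimensionless ratio.
#' @export
reproduction_number <- function(params) {
  stopifnot(inherits(params, "virotherapy_params"))
  bk <- beta_total(params) * params$K
  if (bk + params$gamma <= 0)
    stop("degenerate denominator: beta*K + gamma must be positive", call. = FALSE)
  bk * params$b / (bk + params$gamma)
}

#' Solve the burst size for a target reproduction number
#'
#' Inverts \eqn{R_0 = \beta K b/(\beta K + \gamma)} for \eqn{b}. Scenario
#' descriptions typically fix \eqn{R_0} rather than the burst size, so this
#' is the canonical way to complete a parameter set.
#'
#' @param params a \code{\link{virotherapy_params}} object (its \code{b}
#'   field is ignored).
#' @param target_r0 desired basic reproduction number (> 0).
#' @return Burst size \eqn{b = R_0 (\beta K + \gamma) / (\beta K)}.
#' @export
burst_size_for_r0 <- function(params, target_r0) {
  stopifnot(inherits(params, "virotherapy_params"))
  if (!is.numeric(target_r0) || length(target_r0) != 1L || target_r0 <= 0)
    stop("`target_r0` must be a single positive number", call. = FALSE)
  bk <- beta_total(params) * params$K
  if (bk <= 0) stop("beta*K must be positive to solve for b", call. = FALSE)
  target_r0 * (bk + params$gamma) / bk
}

#' Serialize parameters to a plain list
#'
#' Flat representation used by the YAML/JSON config files: scalar keys
#' \code{r}, \code{K}, \code{rho}, \code{delta}, \code{b}, \code{gamma} and
#' a \code{transmission} list of \code{{beta, tau}} records.
#'
#' @param params a \code{\link{virotherapy_params}} object.
#' @return A nested plain list.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "virotherapy_params"))
  list(
    r = params$r, K = params$K, rho = params$rho, delta = params$delta,
    b = params$b, gamma = params$gamma,
    transmission = purrr::pmap(params$transmission,
                               function(beta, tau) list(beta = beta, tau = tau))
  )
}

#' Deserialize parameters from a plain list
#'
#' Inverse of \code{\link{params_to_list}}. The burst size may be supplied
#' either as \code{b} or indirectly as \code{r0}.
#'
#' @param x nested plain list as produced by \code{\link{params_to_list}} or
#'   read from a YAML/JSON config.
#' @return A \code{\link{virotherapy_params}} object.
#' @export
params_from_list <- function(x) {
  trans <- dplyr::bind_rows(lapply(x$transmission, function(tm)
    tibble::tibble(beta = as.numeric(tm$beta), tau = as.numeric(tm$tau))))
  num <- function(v) if (is.null(v)) NULL else as.numeric(v)
  virotherapy_params(r = num(x$r), K = num(x$K), rho = num(x$rho),
                     delta = num(x$delta), gamma = num(x$gamma),
                     b = num(x$b), r0 = num(x$r0),
                     transmission = trans)
}
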