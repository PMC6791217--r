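# Shared fixtures. Presets are cheap to build; trajectories are cached per
# test run because several files inspect the same ones.

fig_params <- function(name) scenario_preset(name)$params

single_delay_params <- function(tau, r0 = 1.5) {
  virotherapy_params(r0 = r0,
                     transmission = data.frame(beta = c(1e-5, 1e-4),
                                               tau = c(0, tau)))
}

.traj_cache <- new.env(parent = emptyenv())
cached_run <- function(name, t_end = NULL) {
  key <- paste0(name, "_", t_end %||% "default")
  if (is.null(.traj_cache[[key]])) {
    sc <- scenario_preset(name)
    .traj_cache[[key]] <- run_scenario(sc, t_end = t_end)
  }
  .traj_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent root-finding oracle for the positive equilibrium: damped
# Newton on the steady-state equations from a grid of seeds; returns the
# strictly interior root (all components positive, away from E0 and E1).
numeric_equilibrium_oracle <- function(params) {
  f <- function(z) model_rhs(params, c(x = z[1], y = z[2], v = z[3]))
  newton <- function(z) {
    for (k in 1:200) {
      fz <- f(z)
      step <- tryCatch(solve(numeric_jacobian(params, z), fz),
                       error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        znew <- z - lambda * step
        if (max(abs(f(znew))) < max(abs(fz)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      z <- znew
      if (max(abs(f(z))) < 1e-12) return(z)
    }
    NULL
  }
  for (x0 in params$K * c(0.005, 0.02, 0.1, 0.4)) {
    for (v0 in c(1, 30, 300, 3000)) {
      z <- newton(c(x0, 1, v0))
      if (is.null(z)) next
      interior <- all(z > 1e-8) && abs(z[1] - params$K) > 1e-3 * params$K
      if (interior) return(c(x = z[1], y = z[2], v = z[3]))
    }
  }
  stop("oracle found no interior equilibrium")
}

# Finite-difference Jacobian of the undelayed right-hand side.
numeric_jacobian <- function(params, z, h = 1e-6) {
  f <- function(w) model_rhs(params, c(x = w[1], y = w[2], v = w[3]))
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    hp <- h * max(1, abs(z[j]))
    zp <- z; zp[j] <- zp[j] + hp
    zm <- z; zm[j] <- zm[j] - hp
    J[, j] <- (f(zp) - f(zm)) / (2 * hp)
  }
  J
}
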