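test_that("zero-delay spectrum at therapy failure matches the closed form", {
  p3 <- fig_params("fig3")
  s3 <- dfe_spectrum(p3)
  expect_equal(s3$lambda1, -0.206)
  expect_lt(s3$lambda3, 0)
  p5 <- fig_params("fig5")
  expect_gt(dfe_spectrum(p5)$lambda3, 0)
  # eigenvalue oracle: numeric Jacobian at E1 with all delays frozen at zero
  for (p in list(p3, p5)) {
    J <- numeric_jacobian(p, c(p$K, 0, 0))
    ev <- sort(Re(eigen(J, only.values = TRUE)$values))
    s <- dfe_spectrum(p)
    expect_equal(ev, sort(c(s$lambda1, s$lambda2, s$lambda3)),
                 tolerance = 1e-6)
  }
})

test_that("the leading eigenvalue vanishes exactly at the R0 threshold", {
  p <- fig_params("fig3")
  b_crit <- burst_size_for_r0(p, 1)
  p_crit <- virotherapy_params(b = b_crit, transmission = p$transmission)
  expect_lt(abs(dfe_spectrum(p_crit)$lambda3), 1e-9)
  # bisection on b locates the same threshold to 1e-9 relative
  lam3 <- function(b) {
    dfe_spectrum(virotherapy_params(b = b, transmission = p$transmission))$lambda3
  }
  root <- stats::uniroot(lam3, c(0.1, 5), tol = 1e-13)$root
  expect_equal(root, b_crit, tolerance = 1e-9)
})

test_that("delay robustness certificate is issued exactly below threshold", {
  cert3 <- dfe_delay_robustness(fig_params("fig3"))
  expect_true(cert3$certified)
  expect_gt(cert3$a3, 0)
  expect_gte(cert3$a2_min, 0)
  cert5 <- dfe_delay_robustness(fig_params("fig5"))
  expect_false(cert5$certified)
  expect_lt(cert5$a3, 0)
  # single transmission term: no distinct delay pairs, a2 identically zero
  p1 <- virotherapy_params(r0 = 0.5,
                           transmission = data.frame(beta = 1e-4, tau = 2))
  expect_identical(dfe_delay_robustness(p1)$a2_min, 0)
  expect_error(dfe_delay_robustness(p1, numeric(0)), "nonempty")
})

test_that("sum-square expansion identity holds on random vectors", {
  set.seed(42)
  for (k in 1:100) {
    a <- stats::rnorm(sample(2:8, 1), sd = 10)
    lhs <- sum(a)^2
    cross <- 0
    n <- length(a)
    for (i in 1:(n - 1)) for (j in (i + 1):n) cross <- cross + a[i] * a[j]
    rhs <- sum(a^2) + 2 * cross
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("characteristic coefficients agree with the determinant oracle", {
  set.seed(7)
  for (name in c("fig4", "fig5", "fig7")) {
    p <- fig_params(name)
    cf <- characteristic_coefficients(p)
    for (k in 1:20) {
      lam <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
      poly <- characteristic_poly_value(p, lam, coeffs = cf)
      det <- characteristic_value(p, lam, which = "Estar")
      expect_lt(Mod(poly + det) / max(1, Mod(poly)), 1e-9)
    }
  }
})

test_that("single-delay benchmark coefficients take their known values", {
  cf <- characteristic_coefficients(fig_params("fig5"))
  expect_equal(cf$A, 0.51620, tolerance = 1e-4)
  expect_equal(cf$D, 824.70, tolerance = 1e-3)
  expect_equal(cf$E, 1.14580, tolerance = 1e-3)
  expect_equal(cf$C + cf$beta0 * cf$E, -1.010e-5, tolerance = 1e-3)
  expect_equal(cf$K3, -1.30e-8, tolerance = 1e-2)
})

test_that("delayed-term coefficient D collapses to -b*delta*x* in the fusion-free slow-growth limit", {
  p <- virotherapy_params(r = 1e-8, K = 1e6, rho = 1e-10, delta = 0.5,
                          gamma = 0.001, r0 = 1.5,
                          transmission = data.frame(beta = c(1e-5, 1e-4),
                                                    tau = c(0, 5)))
  cf <- characteristic_coefficients(p)
  xs <- cf$equilibrium[["x"]]
  expect_equal(cf$D, -p$b * p$delta * xs, tolerance = 1e-3)
})

test_that("zero-delay Routh-Hurwitz verdicts match the eigenvalues at the endemic point", {
  p4 <- fig_params("fig4")
  rep4 <- endemic_tau0_stability(p4)
  expect_identical(rep4$verdict, "stable")
  for (name in c("fig4", "fig5")) {
    p <- fig_params(name)
    rep <- endemic_tau0_stability(p)
    expect_gt(rep$b1, 0)
    expect_gt(rep$b3, 0)
    # roots of the collapsed cubic = eigenvalues of the numeric Jacobian
    roots <- sort(Re(polyroot(c(rep$b3, rep$b2, rep$b1, 1))))
    es <- endemic_equilibrium(p)
    ev <- sort(Re(eigen(numeric_jacobian(p, es), only.values = TRUE)$values))
    expect_equal(roots, ev, tolerance = 1e-6)
  }
  for (s in 61:70) {
    sc <- random_scenario(s, r0_range = c(1.1, 3), n_delays = 2)
    rep <- endemic_tau0_stability(sc$params)
    expect_gt(rep$b1, 0)
    expect_gt(rep$b3, 0)
  }
})

test_that("delay-independence certificate reduces to constants for one delay", {
  p5 <- fig_params("fig5")
  cf5 <- characteristic_coefficients(p5)
  cert5 <- endemic_delay_condition(p5)
  expect_equal(cert5$K2_min, cf5$K2, tolerance = 1e-12)
  expect_equal(cert5$K3_min, cf5$K3, tolerance = 1e-12)
  expect_lt(cert5$K3_min, 0)
  expect_false(cert5$certified)
  # multi-delay scenario: per-frequency minima are reported
  cert4 <- endemic_delay_condition(fig_params("fig4"))
  expect_true(is.finite(cert4$K2_min) && is.finite(cert4$K3_min))
  expect_identical(cert4$tau0_verdict, "stable")
  expect_error(endemic_delay_condition(p5, numeric(0)), "nonempty")
})

test_that("the transcendental characteristic function has its structural roots", {
  p <- fig_params("fig3")
  # lambda = -r is always a root at the therapy-failure equilibrium
  expect_lt(Mod(characteristic_value(p, -p$r, which = "E1")), 1e-12)
  # lambda = 0 is not a root away from the threshold: constant term
  # -r * delta * (beta K + gamma) * (1 - R0)
  val0 <- characteristic_value(p, 0, which = "E1")
  beta <- beta_total(p)
  expected <- -p$r * p$delta * (beta * p$K + p$gamma) *
    (1 - reproduction_number(p))
  expect_equal(Re(val0), expected, tolerance = 1e-12)
  expect_gt(Mod(val0), 0)
})
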