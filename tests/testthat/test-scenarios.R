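test_that("presets resolve to the documented scenario values", {
  sc3 <- scenario_preset("fig3")
  expect_equal(reproduction_number(sc3$params), 0.7, tolerance = 1e-9)
  expect_equal(sc3$params$transmission$beta, c(1e-3, 1e-5, 2e-5, 3e-5, 4e-5))
  expect_equal(sc3$params$transmission$tau, c(0, 0.2, 1, 2, 3))
  sc4 <- scenario_preset("fig4")
  expect_equal(reproduction_number(sc4$params), 1.5, tolerance = 1e-9)
  expect_identical(sc4$params$transmission, sc3$params$transmission)
  sc7 <- scenario_preset("fig7")
  delayed <- sc7$params$transmission[sc7$params$transmission$tau > 0, ]
  expect_equal(c(delayed$beta, delayed$tau), c(1e-4, 10))
  sc5 <- scenario_preset("fig5")
  expect_identical(sc5$history, c(x = 127, y = 0, v = 30))
  expect_identical(scenario_preset("fig6")$params$transmission$tau[2], 8.8368)
  # Table 1 rates everywhere
  expect_equal(with(sc5$params, c(r, K, rho, delta, gamma)),
               c(0.206, 2139, 0.2145, 0.5115, 0.001))
  expect_error(scenario_preset("fig8"))
})

test_that("random scenarios are deterministic in the seed and hit the R0 range", {
  a <- random_scenario(1)
  b <- random_scenario(1)
  expect_identical(params_to_list(a$params), params_to_list(b$params))
  expect_identical(a$history, b$history)
  for (s in 1:10) {
    lo <- random_scenario(s, r0_range = c(0.2, 0.9))
    r0 <- reproduction_number(lo$params)
    expect_true(r0 >= 0.2 && r0 <= 0.9)
    expect_false(attr(equilibria(lo$params), "exists_endemic"))
    hi <- random_scenario(s + 1000, r0_range = c(1.1, 3.0))
    expect_true(attr(equilibria(hi$params), "exists_endemic"))
  }
})

test_that("random scenario generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(random_scenario(7))
  expect_identical(stats::runif(1), before)
})

test_that("cli simulate writes a trajectory CSV and a summary JSON", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fig3run")
  status <- run_cli(c("simulate", "--scenario", "fig3", "--t-end", "300",
                      "--out", out))
  expect_identical(status, 0L)
  traj <- utils::read.csv(paste0(out, ".csv"))
  expect_identical(names(traj), c("t", "x", "y", "v"))
  summ <- jsonlite::read_json(paste0(out, "_summary.json"))
  expect_equal(summ$r0, 0.7, tolerance = 1e-9)
})

test_that("cli stability reports the subthreshold certificate", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "stab.json")
  status <- run_cli(c("stability", "--scenario", "fig3", "--out", out))
  expect_identical(status, 0L)
  rep <- jsonlite::read_json(out)
  expect_equal(rep$r0, 0.7, tolerance = 1e-9)
  expect_true(rep$dfe_robustness$certified)
})

test_that("cli hopf reports the critical delay and the preset discrepancy", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "hopf.json")
  status <- run_cli(c("hopf", "--scenario", "fig6", "--out", out))
  expect_identical(status, 0L)
  rep <- jsonlite::read_json(out)
  expect_equal(rep$tau_star, 8.8368, tolerance = 5e-3)
  expect_lt(abs(rep$stored_delay_minus_tau_star), 0.05)
})

test_that("cli rejects malformed invocations with status 2", {
  expect_identical(suppressMessages(run_cli(character(0))), 2L)
  expect_identical(suppressMessages(run_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(run_cli(c("hopf-scan", "--scenario", "fig5"))), 2L)
  expect_identical(
    suppressMessages(run_cli(c("simulate", "--scenario", "fig9"))), 2L)
})

test_that("cli reproduce is idempotent and reports the critical delay", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  expect_identical(run_cli(c("reproduce", "--out-dir", dir1)), 0L)
  expect_identical(run_cli(c("reproduce", "--out-dir", dir2)), 0L)
  for (f in c("fig3.csv", "reproduce.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  rep <- jsonlite::read_json(file.path(dir1, "reproduce.json"))
  expect_equal(rep$hopf$tau_star, 8.8368, tolerance = 5e-3)
  expect_equal(rep$fig3$terminal_state$x, 2139, tolerance = 1e-3)
  expect_identical(rep$fig3$converged_to, "E1")
  expect_identical(rep$fig4$converged_to, "Estar")
  expect_identical(rep$fig7$converged_to, "cycle")
})

test_that("cli round-trips a config file", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "scenario.yaml")
  write_scenario_config(scenario_preset("fig3"), cfg)
  out <- file.path(dir, "cfgrun")
  status <- run_cli(c("simulate", "--config", cfg, "--t-end", "100",
                      "--out", out))
  expect_identical(status, 0L)
  expect_true(file.exists(paste0(out, ".csv")))
})
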