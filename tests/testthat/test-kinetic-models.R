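test_that("uptake starts at the initial condition and zero rate stays at zero", {
  m1 <- kinetic_model("uptake")
  m2 <- kinetic_model("uptake_response")
  p <- kinetic_params(Kup = 0.4, Kresp = 0.1)
  sol <- solve_kinetics(m1, p, c(0, 1, 5))
  expect_identical(unname(sol$values[1L, "Nb"]), 0)

  p0 <- kinetic_params(Kup = 0, Kresp = 0.3)
  sol0 <- solve_kinetics(m2, p0, seq(0, 48, 4))
  expect_true(all(sol0$values == 0))
})

test_that("numerical integration matches the saturating-uptake closed form", {
  # single derived point: Nb(4) = Nrecp (1 - exp(-Kup D t)) = 1 - e^-1
  p <- kinetic_params(Kup = 0.25, D = 1, Nrecp = 1)
  sol <- solve_kinetics(kinetic_model("uptake"), p, c(0, 4))
  expect_equal(unname(sol$values[2L, "Nb"]), 1 - exp(-1), tolerance = 1e-8)

  # 100 random parameter draws, relative agreement <= 1e-6
  set.seed(11)
  for (i in 1:100) {
    p <- kinetic_params(Kup = runif(1, 0.01, 2), Nrecp = runif(1, 0.1, 5),
                        D = runif(1, 0.1, 3))
    times <- sort(runif(8, 0.1, 72))
    num <- solve_kinetics(kinetic_model("uptake"), p, times)$values[, "Nb"]
    ana <- closed_form_uptake(p, times)$values[, "Nb"]
    expect_lt(max(abs(num - ana) / pmax(abs(ana), 1e-12)), 1e-6)
  }
})

test_that("closed-form uptake evaluates its limits and stated values", {
  p <- kinetic_params(Kup = 0.16, D = 1, Nrecp = 2)
  expect_identical(unname(closed_form_uptake(p, c(0, 10))$values[1L, "Nb"]), 0)
  expect_equal(unname(closed_form_uptake(p, c(0, 10))$values[2L, "Nb"]),
               2 * (1 - exp(-1.6)), tolerance = 1e-12)
  # saturation limit
  expect_equal(unname(closed_form_uptake(p, c(0, 1e5))$values[2L, "Nb"]), 2,
               tolerance = 1e-9)
})

test_that("trajectories respect capacity bounds, monotonicity and response lag", {
  set.seed(22)
  m <- kinetic_model("uptake_response")
  for (i in 1:20) {
    p <- kinetic_params(Kup = runif(1, 0.05, 1), Kresp = runif(1, 0.01, 0.5),
                        Nrecp = runif(1, 0.2, 3), Nresp = runif(1, 0.2, 3))
    times <- seq(0, 72, 2)
    v <- solve_kinetics(m, p, times)$values
    expect_true(all(v[, "Nb"] <= p[["Nrecp"]] + 1e-7))
    expect_true(all(v[, "Nr"] <= p[["Nresp"]] + 1e-7))
    expect_true(all(diff(v[, "Nb"]) >= -1e-9))
    expect_true(all(diff(v[, "Nr"]) >= -1e-9))
    # response lags the fully-driven bound: Nb < Nrecp at finite t implies
    # Nr(t) < Nresp (1 - exp(-Kresp Nrecp t))
    bound <- p[["Nresp"]] * (1 - exp(-p[["Kresp"]] * p[["Nrecp"]] * times))
    expect_true(all(v[-1L, "Nr"] < bound[-1L] + 1e-9))
  }
})

test_that("invalid parameters and grids are rejected with clear errors", {
  m <- kinetic_model("uptake")
  expect_error(kinetic_params(Kup = -0.1), "negative")
  expect_error(kinetic_params(Kup = NaN), "non-finite")
  expect_error(solve_kinetics(m, c(Kup = 0.1, Nrecp = 1), c(0, 1)), "missing")
  expect_error(solve_kinetics(m, kinetic_params(), c(1, 1, 2)),
               "strictly increasing")
  expect_error(solve_kinetics(m, kinetic_params(), c(-1, 2)), "after 0")
})

test_that("a model declared from rate expressions matches the built-in system", {
  decl <- custom_kinetic_model(
    "uptake_response_decl", c("Nb", "Nr"),
    c("(Nrecp - Nb) * Kup * D", "(Nresp - Nr) * Kresp * Nb"),
    param_names = c("Kup", "Kresp", "Nrecp", "Nresp", "D"))
  p <- kinetic_params(Kup = 0.3, Kresp = 0.08, Nrecp = 1.5, Nresp = 0.8)
  times <- seq(0, 48, 3)
  ref <- solve_kinetics(kinetic_model("uptake_response"), p, times)$values
  got <- solve_kinetics(decl, p, times)$values
  expect_equal(got, ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rate expressions are parsed against a whitelist, not executed", {
  expect_error(
    custom_kinetic_model("bad", "Nb", "system('ls')", param_names = "Kup"),
    "disallowed function")
  expect_error(
    custom_kinetic_model("bad", "Nb", "Kup * Unknown", param_names = "Kup"),
    "unknown symbol")
})
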