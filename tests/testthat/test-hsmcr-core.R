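test_that("lack of fit reproduces hand-computed residuals", {
  C <- matrix(c(1, 0, 0, 1), 2, 2)
  S <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  D <- C %*% S
  expect_identical(lack_of_fit(D, C, S)$ssr, 0)
  expect_identical(lack_of_fit(D, 0 * C, S)$ssr, sum(D^2))
  # D = I, reconstruction [[1,1],[0,1]]: one off-by-one entry
  D2 <- diag(2)
  R2 <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  expect_identical(lack_of_fit(D2, diag(2), R2)$ssr, 1)
  expect_equal(lack_of_fit(D2, diag(2), R2)$lof_pct, 100 * sqrt(1 / 2),
               tolerance = 1e-12)
})

test_that("convergence rule stops on 20 quiet iterations or at iteration 200", {
  # constant error for 21 iterations: 20 consecutive sub-1% changes
  expect_identical(check_convergence(rep(5, 21), 0.01, 20, 200),
                   "stop_patience")
  expect_identical(check_convergence(rep(5, 20), 0.01, 20, 200), "continue")
  # halving every step is a 50% change: never quiet
  expect_identical(check_convergence(5 * 0.5^(0:49), 0.01, 20, 200),
                   "continue")
  expect_identical(check_convergence(5 * 0.5^(0:199), 0.01, 20, 200),
                   "stop_max_iter")
  # a rise below 1% counts as quiet too
  hist <- 5 * cumprod(c(1, rep(1.005, 20)))
  expect_identical(check_convergence(hist, 0.01, 20, 200), "stop_patience")
  # perfect fit converges immediately
  expect_identical(check_convergence(c(3, 0), 0.01, 20, 200), "stop_patience")
})

test_that("kinetic refit is a fixed point at the truth and recovers far starts", {
  times <- seq(0, 72, 0.5)
  m <- kinetic_model("uptake")
  k_star <- kinetic_params(Kup = 0.25, Nrecp = 1.2)
  C_exact <- solve_kinetics(m, k_star, times)$values

  fix <- fit_kinetic_constants(C_exact, m, k_star, times, components = 1L)
  expect_equal(unclass(fix$k)[c("Kup", "Nrecp")],
               unclass(k_star)[c("Kup", "Nrecp")], tolerance = 1e-8)

  far <- fit_kinetic_constants(C_exact, m, kinetic_params(Kup = 2, Nrecp = 0.3),
                               times, components = 1L)
  rel <- abs(far$k[c("Kup", "Nrecp")] - k_star[c("Kup", "Nrecp")]) /
    k_star[c("Kup", "Nrecp")]
  expect_lt(max(rel), 1e-3)

  # with noise: the refit never ends worse than its warm start
  set.seed(41)
  C_noisy <- C_exact + matrix(rnorm(length(C_exact), sd = 0.01),
                              nrow(C_exact))
  k_prev <- kinetic_params(Kup = 0.4, Nrecp = 0.9)
  prev_ssr <- sum((solve_kinetics(m, k_prev, times)$values - C_noisy)^2)
  refit <- fit_kinetic_constants(C_noisy, m, k_prev, times, components = 1L)
  expect_lte(refit$ssr, prev_ssr + 1e-12)
})

test_that("hard substitution replaces linked columns and passes others through", {
  C_soft <- matrix(rnorm(30), 10, 3)
  expect_identical(apply_kinetic_constraint(C_soft, NULL), C_soft)
  C_model <- matrix(1, 10, 2)
  C_hard <- apply_kinetic_constraint(C_soft, C_model, components = c(1L, 2L))
  expect_identical(C_hard[, 3], C_soft[, 3])
  expect_identical(C_hard[, 1:2], C_model)
  # all components constrained: full replacement
  expect_identical(apply_kinetic_constraint(C_soft[, 1:2], C_model),
                   C_model)
})

test_that("a consistent (C, S, k) triple is a fixed point of one iteration", {
  times <- seq(0, 72, 1.5)
  m <- kinetic_model("uptake_response")
  k_star <- kinetic_params()
  lib <- default_library()
  C <- cbind(solve_kinetics(m, k_star, times)$values, 1)
  S <- rbind(lib$binding_signature, lib$response_signature, lib$cell_spectrum)
  D <- C %*% S
  ds <- spectra_dataset(D, times, lib$wavenumbers)
  cfg <- constraint_config(
    3, kinetic = list(model = m, k0 = k_star), max_iter = 1L)
  fit <- run_mcr_als(ds, cfg, normalize = FALSE)
  expect_equal(fit$C, C, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$S, S, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(fit$k_final), unclass(k_star), tolerance = 1e-8)
  expect_lt(fit$lof_pct_history[1], 1e-8)
})

test_that("soft-only ALS error is monotone non-increasing", {
  set.seed(42)
  for (rep in 1:50) {
    inst <- random_bilinear()
    ds <- spectra_dataset(abs(inst$D), seq_len(nrow(inst$D)) - 1,
                          seq_len(ncol(inst$D)) * 10 + 400)
    cfg <- constraint_config(2, max_iter = 15L, patience = 5L)
    # some random instances legitimately shed a component (warned); the
    # error monotonicity must hold regardless
    fit <- suppressWarnings(run_mcr_als(ds, cfg, normalize = FALSE))
    expect_true(all(diff(fit$lof_history) <= 1e-9 * fit$lof_history[1]))
  }
})

test_that("hard-constrained histories stay finite and the stop rule fires", {
  sim <- simulate_dataset(config = small_sim_config(seed = 8))
  cfg <- constraint_config(3, kinetic = list(
    model = kinetic_model("uptake_response"), k0 = far_k0()), max_iter = 60L)
  fit <- run_mcr_als(sim$dataset, cfg)
  expect_true(all(is.finite(fit$lof_history)))
  expect_true(fit$stop_reason %in% c("patience", "max_iter"))
  expect_identical(length(fit$lof_history), fit$n_iter)
  expect_identical(nrow(fit$k_history), fit$n_iter)
})

test_that("reconstruction is invariant under the intensity ambiguity", {
  sim <- simulate_dataset(config = small_sim_config(seed = 9))
  cfg <- constraint_config(3, kinetic = list(
    model = kinetic_model("uptake_response"), k0 = far_k0()), max_iter = 25L)
  fit <- run_mcr_als(sim$dataset, cfg)
  recon <- fit$C %*% fit$S
  alpha <- 3.2
  C2 <- fit$C; S2 <- fit$S
  C2[, 1] <- C2[, 1] / alpha
  S2[1, ] <- S2[1, ] * alpha
  expect_equal(C2 %*% S2, recon, tolerance = 1e-10)
})

test_that("sparse time grids trigger an identifiability warning", {
  times <- c(0, 1, 2, 4, 6, 12)           # 6 points, 4 free parameters
  m <- kinetic_model("uptake_response")
  k <- kinetic_params()
  lib <- default_library()
  C <- cbind(solve_kinetics(m, k, times)$values, 1)
  S <- rbind(lib$binding_signature, lib$response_signature, lib$cell_spectrum)
  ds <- spectra_dataset(C %*% S, times, lib$wavenumbers)
  cfg <- constraint_config(3, kinetic = list(model = m, k0 = k),
                           max_iter = 2L)
  expect_warning(run_mcr_als(ds, cfg, normalize = FALSE), "identifiable")
})
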