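test_that("band area of a triangular peak matches the hand trapezoid", {
  # triangle spanning exactly the 988-1023 band (width 35, height 1 at the
  # apex 1005.5); kinks are grid points so the trapezoid rule is exact and
  # the hand value is (1/2) * 35 * 1 = 17.5. Anchor-window points all sit at
  # zero, so the fitted baseline is the zero line.
  wn <- c(980, 984, 986, 987, 988, 1005.5, 1023, 1024.5, 1026, 1030)
  tri <- function(w) pmax(0, 1 - abs(w - 1005.5) / 17.5)
  y <- tri(wn)
  expect_equal(phenylalanine_area(y, wn), 17.5, tolerance = 1e-12)
  # constant offsets are absorbed by the baseline
  expect_equal(phenylalanine_area(y + 3.7, wn), 17.5, tolerance = 1e-10)
})

test_that("band area is linear in the spectrum for fixed anchors", {
  lib <- default_library()
  wn <- lib$wavenumbers
  a1 <- phenylalanine_area(lib$cell_spectrum, wn)
  expect_equal(phenylalanine_area(2.5 * lib$cell_spectrum, wn), 2.5 * a1,
               tolerance = 1e-10)
  extra <- gaussian_bands(wn, data.frame(center = 1005, fwhm = 10, height = 0.3))
  expect_equal(phenylalanine_area(lib$cell_spectrum + extra, wn),
               a1 + phenylalanine_area(extra, wn), tolerance = 1e-10)
})

test_that("spectra without a reference band raise a degenerate-band error", {
  wn <- seq(950, 1050, 2)
  expect_error(phenylalanine_area(rep(2, length(wn)), wn), "degenerate")
  # a dataset containing such a row reports its index
  lib <- default_library()
  m <- rbind(lib$cell_spectrum, 0 * lib$cell_spectrum + 1)
  ds <- spectra_dataset(m, c(0, 1), lib$wavenumbers)
  expect_error(normalize_dataset(ds), "row 2")
})

test_that("normalization is idempotent, scale invariant and exact", {
  sim <- simulate_dataset(config = simulation_config(seed = 3))
  nd <- normalize_dataset(sim$dataset)
  areas <- vapply(seq_len(nrow(nd$intensities)), function(i) {
    phenylalanine_area(nd$intensities[i, ], nd$wavenumbers)
  }, numeric(1))
  expect_equal(areas, rep(1, length(areas)), tolerance = 1e-10)

  # idempotence
  nd2 <- normalize_dataset(nd)
  expect_equal(nd2$intensities, nd$intensities, tolerance = 1e-12)

  # per-row scaling washes out
  scaled <- sim$dataset
  scaled$intensities[3, ] <- 5 * scaled$intensities[3, ]
  nds <- normalize_dataset(scaled)
  expect_equal(nds$intensities[3, ], nd$intensities[3, ], tolerance = 1e-12)
})

test_that("singular spectrum is non-increasing with unit-sum variance fractions", {
  set.seed(4)
  # exactly rank-2 noiseless matrix
  m <- matrix(runif(20), 10, 2) %*% matrix(runif(12), 2, 6)
  rk <- estimate_rank(m)
  expect_identical(rk$n_above(1e-10), 2L)
  expect_true(all(diff(rk$singular_values) <= 0))
  expect_equal(sum(rk$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(rk$cumulative_variance[length(rk$cumulative_variance)], 1,
               tolerance = 1e-12)
})

test_that("initial concentration estimates follow the kinetic model", {
  times <- seq(0, 36, 3)
  m <- kinetic_model("uptake_response")

  # unconstrained-only request: column of ones
  C0 <- initial_concentrations(kinetic_model("uptake"),
                               kinetic_params(Kup = 0), times,
                               n_components = 2, constrained_indices = 1L)
  expect_identical(C0[, 1L], rep(0, length(times)))  # Kup = 0 stays at zero
  expect_identical(C0[, 2L], rep(1, length(times)))

  k <- kinetic_params(Kup = 0.3, Kresp = 0.07)
  C0 <- initial_concentrations(m, k, times, n_components = 3)
  ref <- solve_kinetics(m, k, times)$values
  expect_equal(C0[, 1:2], ref, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(initial_concentrations(m, k, times, 3,
                                      constrained_indices = c(1, 1)),
               "distinct")
  expect_error(initial_concentrations(m, k, times, 2,
                                      constrained_indices = c(1, 3)),
               "within")
})
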