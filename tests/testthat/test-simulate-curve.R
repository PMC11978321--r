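test_that("identical parameters and seed give bit-identical curves", {
  p <- synth_curve_params(E_true = 113)
  a <- simulate_curve(p, seed = 7)
  b <- simulate_curve(p, seed = 7)
  expect_identical(a$approach, b$approach)
  expect_identical(a$retract, b$retract)
  c <- simulate_curve(p, seed = 8)
  expect_false(identical(a$approach$d_m, c$approach$d_m))
})

test_that("noiseless forward model reproduces the contact model exactly", {
  for (kind in c("paraboloid", "sneddon_sphere")) {
    p <- synth_curve_params(E_true = 100, noise_sd = 0, model = kind)
    cu <- simulate_curve(p, seed = 1)
    m <- contact_model(kind, R = p$R, nu = p$nu)
    h_c <- attr(cu, "h_c_true")
    F <- cu$k * cu$approach$d_m
    h <- cu$approach$z_m - cu$approach$d_m
    delta <- pmax(h_c - h, 0)
    expect_equal(F, contact_force(delta + 1e-30, m, 100), tolerance = 1e-9)
  }
})

test_that("approach terminates at the set point and spans a valid indentation", {
  p <- synth_curve_params(E_true = 113)
  cu <- simulate_curve(p, seed = 1)
  F <- cu$k * cu$approach$d_m
  n <- length(F)
  expect_gte(F[n], p$setpoint - 3 * p$noise_sd)   # last sample at set point
  # maximum indentation in the 300 nm - 2.5 um window at 1 nN
  h_c <- attr(cu, "h_c_true")
  delta_max <- h_c - (cu$approach$z_m[n] - cu$approach$d_m[n])
  expect_gt(delta_max, 300e-9)
  expect_lt(delta_max, 2.5e-6)
})

test_that("stiffer cells are indented less at the same set point", {
  dm <- sapply(c(50, 113, 300, 800), function(E) {
    p <- synth_curve_params(E_true = E, noise_sd = 0)
    cu <- simulate_curve(p, seed = 1)
    n <- nrow(cu$approach)
    attr(cu, "h_c_true") - (cu$approach$z_m[n] - cu$approach$d_m[n])
  })
  expect_true(all(diff(dm) < 0))
})

test_that("an unreachable set point is rejected with the required travel", {
  p <- synth_curve_params(E_true = 5)   # ultrasoft: needs > 3.5 um of travel
  expect_error(simulate_curve(p, seed = 1), "unreachable")
  expect_error(simulate_curve(p, seed = 1), "um of")
})

test_that("the first-indentation shift only affects curve #1", {
  p <- synth_curve_params(E_true = 100, noise_sd = 0)
  ms <- contact_model("sneddon_sphere")
  curves <- simulate_cell(100, p, n_curves = 4, first_shift_factor = 0.7,
                          seed = 1)
  Es <- sapply(curves, function(cu) correct_and_fit(cu, ms)$E)
  expect_equal(Es[1] / Es[2], 0.7, tolerance = 1e-3)
  expect_equal(Es[2], Es[3], tolerance = 1e-6)
  expect_equal(Es[2], 100, tolerance = 1e-3)
  # no shift: all curves share E_true
  curves1 <- simulate_cell(100, p, n_curves = 3, first_shift_factor = 1,
                           seed = 1)
  Es1 <- sapply(curves1, function(cu) correct_and_fit(cu, ms)$E)
  expect_equal(max(Es1) - min(Es1), 0, tolerance = 1e-4)
})

test_that("cohort bundles have the stated structure and determinism", {
  cp <- cohort_params(groups = list(list(label = "A", median_E = 113,
                                         log_sd = 0.3, n_cells = 1)),
                      curves_per_cell = 15, outlier_fraction = 0, seed = 3,
                      curve_params = fast_curve_params())
  b <- simulate_cohort(cp)
  expect_equal(length(b$curves), 15L)            # n_cells * curves_per_cell
  expect_equal(nrow(b$truth), 1L)
  expect_false(any(b$truth$outlier))
  b2 <- simulate_cohort(cp)
  expect_identical(lapply(b$curves, `[[`, "approach"),
                   lapply(b2$curves, `[[`, "approach"))
})

test_that("per-cell moduli are log-normal around the group median", {
  x <- draw_cell_moduli(113, 0.3, 500, seed = 11)
  expect_true(all(x > 0))
  expect_equal(median(x), 113, tolerance = 0.05)
})
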