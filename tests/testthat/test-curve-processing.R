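test_that("baseline offset and noise are recovered from a known injection", {
  p <- synth_curve_params(E_true = 113, baseline_offset = 50e-12)
  cu <- simulate_curve(p, seed = 5)
  b <- detect_baseline(cu)
  expect_equal(b$offset, 50e-12, tolerance = 0.08)   # within noise/sqrt(n)
  expect_equal(b$noise_sd, 10e-12, tolerance = 0.25)
  expect_false(b$short_baseline)

  p0 <- synth_curve_params(E_true = 113, baseline_offset = 50e-12, noise_sd = 0)
  b0 <- detect_baseline(simulate_curve(p0, seed = 1))
  expect_equal(b0$offset, 50e-12, tolerance = 1e-9)
  expect_equal(b0$noise_sd, 0)
})

test_that("a 350 nm baseline raises the short_baseline condition", {
  p <- synth_curve_params(E_true = 113, contact_frac = 0.1)  # 350 nm of 3.5 um
  b <- detect_baseline(simulate_curve(p, seed = 1))
  expect_true(b$short_baseline)
  f <- correct_and_fit(simulate_curve(p, seed = 1), contact_model())
  expect_true("short_baseline" %in% f$qc$flags)
  expect_false(qc_pass(f))
})

test_that("contact point: exact on noiseless data, nonconvergent without contact", {
  p <- synth_curve_params(E_true = 113, noise_sd = 0)
  cu <- simulate_curve(p, seed = 1)
  b <- detect_baseline(cu)
  h0 <- estimate_contact_point(cu, b)
  # within one sample spacing (the tip-position grid is the piezo grid
  # shifted by the tiny bending correction)
  expect_lt(abs(h0 - attr(cu, "h_c_true")), 1.2 * p$sample_spacing)

  # pure-noise curve: force never rises above the noise
  set.seed(1)
  z <- seq(3.5e-6, 0, by = -5e-9)
  fc <- force_curve(data.frame(z_m = z, d_m = rnorm(length(z), 0, 1e-11) / 0.06),
                    k = 0.06)
  bn <- detect_baseline(fc)
  expect_error(estimate_contact_point(fc, bn), "nonconvergent")
})

test_that("contact point error stays below 50 nm at instrument noise", {
  err <- sapply(1:100, function(s) {
    p <- synth_curve_params(E_true = 113)
    cu <- simulate_curve(p, seed = s)
    abs(estimate_contact_point(cu, detect_baseline(cu)) - attr(cu, "h_c_true"))
  })
  expect_lt(quantile(err, 0.95), 50e-9)
})

test_that("noiseless round trips recover E within 0.1% for both models", {
  for (kind in c("paraboloid", "sneddon_sphere")) {
    p <- synth_curve_params(E_true = 100, noise_sd = 0, model = kind)
    fit <- correct_and_fit(simulate_curve(p, seed = 1), contact_model(kind))
    expect_equal(fit$E, 100, tolerance = 1e-3)
    expect_true(qc_pass(fit))
  }
})

test_that("noisy fits are unbiased at instrument noise", {
  ms <- contact_model("sneddon_sphere")
  Es <- sapply(1:30, function(s)
    correct_and_fit(simulate_curve(synth_curve_params(E_true = 113), seed = s),
                    ms)$E)
  expect_equal(mean(Es), 113, tolerance = 0.05)
  expect_lt(sd(Es), 5)
})

test_that("fits are scale- and shift-equivariant", {
  p <- synth_curve_params(E_true = 100, noise_sd = 0)
  cu <- simulate_curve(p, seed = 1)
  ms <- contact_model("sneddon_sphere")
  f0 <- correct_and_fit(cu, ms)
  # force scale: multiply deflections (hence forces) by c.
  # h = z - d changes too, so rebuild z to keep tip positions identical.
  c_ <- 1.7
  cu2 <- cu
  cu2$approach$z_m <- cu$approach$z_m + (c_ - 1) * cu$approach$d_m
  cu2$approach$d_m <- c_ * cu$approach$d_m
  f2 <- correct_and_fit(cu2, ms)
  expect_equal(f2$E, c_ * f0$E, tolerance = 1e-3)
  # z shift: contact point shifts with it, E unchanged
  cu3 <- cu
  cu3$approach$z_m <- cu$approach$z_m + 250e-9
  f3 <- correct_and_fit(cu3, ms)
  expect_equal(f3$E, f0$E, tolerance = 1e-4)
  expect_equal(f3$contact_point - f0$contact_point, 250e-9, tolerance = 1e-3)
})

test_that("the joint fit matches a brute-force grid search of the residual surface", {
  p <- synth_curve_params(E_true = 100, noise_sd = 0, model = "paraboloid")
  cu <- simulate_curve(p, seed = 1)
  mp <- contact_model("paraboloid")
  fit <- correct_and_fit(cu, mp)
  # independent oracle: exhaustive SSR over an (E, h_c) grid
  F <- cu$k * cu$approach$d_m
  h <- cu$approach$z_m - cu$approach$d_m
  h_grid <- seq(fit$contact_point - 20e-9, fit$contact_point + 20e-9,
                length.out = 81)
  E_grid <- seq(90, 110, length.out = 81)
  ssr <- outer(E_grid, h_grid, Vectorize(function(E, hc) {
    sum((F - contact_force(pmax(hc - h, 0), mp, E))^2)
  }))
  best <- arrayInd(which.min(ssr), dim(ssr))
  expect_equal(E_grid[best[1]], fit$E, tolerance = 0.01)
  expect_equal(h_grid[best[2]], fit$contact_point, tolerance = 1e-2)
})

test_that("cross-model fits show the documented sign-consistent bias", {
  # sphere unit force < paraboloid unit force, so fitting sphere to
  # paraboloid-generated data inflates E, and vice versa
  p <- synth_curve_params(E_true = 100, noise_sd = 0, model = "paraboloid")
  cu <- simulate_curve(p, seed = 1)
  expect_gt(correct_and_fit(cu, contact_model("sneddon_sphere"))$E, 100)
  ps <- synth_curve_params(E_true = 100, noise_sd = 0, model = "sneddon_sphere")
  cus <- simulate_curve(ps, seed = 1)
  expect_lt(correct_and_fit(cus, contact_model("paraboloid"))$E, 100)
})

test_that("membrane pinches are detected at threshold semantics", {
  # deterministic: noiseless planted pinch of 100 pN depth, 30 nm width
  p <- synth_curve_params(E_true = 113, noise_sd = 0,
                          pinch = list(depth = 100e-12, width = 30e-9,
                                       position = 400e-9))
  f <- correct_and_fit(simulate_curve(p, seed = 1), contact_model())
  expect_true("pinch" %in% f$qc$flags)
  expect_false(qc_pass(f))
  # a 20 pN drop stays below the 50 pN threshold
  p2 <- synth_curve_params(E_true = 113, noise_sd = 0,
                           pinch = list(depth = 20e-12, width = 30e-9,
                                        position = 400e-9))
  f2 <- correct_and_fit(simulate_curve(p2, seed = 1), contact_model())
  expect_false("pinch" %in% f2$qc$flags)
  # clean noisy curves: no false positives over 30 seeds
  fp <- sapply(1:30, function(s)
    "pinch" %in% correct_and_fit(simulate_curve(synth_curve_params(E_true = 113),
                                                seed = s),
                                 contact_model())$qc$flags)
  expect_lt(mean(fp), 0.05)
})

test_that("the depth-ratio warning is advisory only", {
  p <- synth_curve_params(E_true = 113, noise_sd = 0)
  cu <- simulate_curve(p, seed = 1)
  f <- correct_and_fit(cu, contact_model(), cell_diameter = 10e-6)
  expect_true("depth_ratio_warn" %in% f$qc$flags)   # ~1.3 um > 10% of 10 um
  expect_true(qc_pass(f))
})
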