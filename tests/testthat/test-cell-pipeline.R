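test_that("the per-cell protocol averages curves 2..15 and drops the first", {
  fits <- c(list(make_fit(70, 1)), lapply(2:15, function(i) make_fit(100, i)))
  cr <- assess_cell(fits)
  expect_true(cr$included)
  expect_equal(cr$n_curves_passing_qc, 15L)
  expect_equal(cr$n_curves_averaged, 14L)
  expect_equal(cr$E_cell, 100)           # first indentation (70) removed
  expect_equal(cr$E_first, 70)
})

test_that("cells with fewer than 11 QC survivors are excluded", {
  flags <- c(rep(list("short_baseline"), 5), rep(list(character(0)), 10))
  fits <- lapply(1:15, function(i) make_fit(100, i, flags = flags[[i]]))
  cr <- assess_cell(fits)
  expect_false(cr$included)
  expect_match(cr$reason, "fewer than 11")
  expect_equal(cr$n_curves_passing_qc, 10L)
  expect_true(is.na(cr$E_cell))
})

test_that("a failed first curve is a no-op at step 3; the >= 10 bound is enforced after it", {
  # first curve fails QC: 11 survivors remain from indices 2..12, averaged = 11
  flags <- c(list("pinch"), rep(list(character(0)), 11),
             rep(list("pinch"), 3))
  fits <- lapply(1:15, function(i) make_fit(100 + i, i, flags = flags[[i]]))
  cr <- assess_cell(fits)
  expect_true(cr$included)
  expect_equal(cr$n_curves_passing_qc, 11L)
  expect_equal(cr$n_curves_averaged, 11L)
  expect_equal(cr$E_cell, mean(100 + 2:12))
  # 11 survivors but first among them: 10 averaged -> still included
  flags2 <- c(rep(list(character(0)), 11), rep(list("pinch"), 4))
  fits2 <- lapply(1:15, function(i) make_fit(100, i, flags = flags2[[i]]))
  cr2 <- assess_cell(fits2)
  expect_true(cr2$included)
  expect_equal(cr2$n_curves_averaged, 10L)
  # 10 survivors post-QC: excluded before the first-curve step
  flags3 <- c(rep(list(character(0)), 10), rep(list("pinch"), 5))
  fits3 <- lapply(1:15, function(i) make_fit(100, i, flags = flags3[[i]]))
  expect_false(assess_cell(fits3)$included)
})

test_that("E_cell is permutation-invariant and independent of curve #1", {
  fits <- c(list(make_fit(999, 1)), lapply(2:15, function(i) make_fit(i * 10, i)))
  e1 <- assess_cell(fits)$E_cell
  set.seed(1)
  e2 <- assess_cell(sample(fits))$E_cell
  expect_equal(e1, e2)
  fits2 <- c(list(make_fit(-5, 1)), fits[-1])
  fits2[[1]]$E <- 1e4
  expect_equal(assess_cell(fits2)$E_cell, e1)
})

test_that("metadata exclusions and malformed input are handled", {
  fits <- lapply(1:15, function(i) make_fit(100, i))
  cr <- assess_cell(fits, metadata = list(moved_or_morphology_excluded = TRUE))
  expect_false(cr$included)
  expect_match(cr$reason, "moved or morphology")
  expect_error(assess_cell(list()), "empty")
  expect_error(assess_cell(c(fits, list(make_fit(1, 3)))), "duplicate")
})

test_that("first-indentation-only mode averages curve #1 alone", {
  fits <- c(list(make_fit(70, 1)), lapply(2:15, function(i) make_fit(100, i)))
  cr <- assess_cell(fits, first_only = TRUE)
  expect_true(cr$included)
  expect_equal(cr$E_cell, 70)
  expect_equal(cr$n_curves_averaged, 1L)
  # first curve failed QC: nothing to analyze
  fits2 <- c(list(make_fit(70, 1, flags = "pinch")),
             lapply(2:15, function(i) make_fit(100, i)))
  expect_false(assess_cell(fits2, first_only = TRUE)$included)
})

test_that("run_bundle dispositions every cell exactly once", {
  cp <- cohort_params(groups = list(list(label = "A", median_E = 113,
                                         log_sd = 0.3, n_cells = 3),
                                    list(label = "B", median_E = 171,
                                         log_sd = 0.3, n_cells = 3)),
                      seed = 2, curve_params = fast_curve_params())
  b <- simulate_cohort(cp)
  res <- run_bundle(b, config = fast_config())
  df <- cell_table(res$cells)
  expect_equal(nrow(df), 6L)
  expect_equal(sum(df$included) + sum(!df$included), 6L)
  expect_true(all(df$included))          # no artifacts planted
  expect_equal(length(res$fits), length(b$curves))
  # recovered cell moduli track the generator's truth
  tr <- b$truth[match(df$cell_id, b$truth$cell_id), ]
  expect_equal(df$E_cell_Pa, tr$E_true_Pa, tolerance = 0.05)
})

test_that("a cell with 6 of 15 curves carrying short baselines is excluded", {
  p <- fast_curve_params(E_true = 113)
  artifact <- c(rep(list(list(short_baseline = TRUE)), 6),
                rep(list(NULL), 9))
  curves <- simulate_cell(113, p, n_curves = 15, first_shift_factor = 0.7,
                          seed = 4, cell_id = "sb", artifact = artifact)
  fits <- lapply(curves, correct_and_fit, model = contact_model("paraboloid"))
  expect_equal(sum(!sapply(fits, qc_pass)), 6L)
  cr <- assess_cell(fits)
  expect_false(cr$included)      # 9 survivors < 11
  expect_match(cr$reason, "fewer than 11")
})
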