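test_that("Tukey fences match the hand-computed examples", {
  os <- detect_outliers(c(10, 11, 12, 13, 100))
  expect_equal(os$q1, 11)
  expect_equal(os$q3, 13)
  expect_equal(os$iqr, 2)
  expect_equal(os$fences, c(8, 16))
  expect_equal(os$outlier_values, 100)
  expect_true(all(abs(os$z_scores) >= 3))   # leave-one-out z of 100 is ~68
  expect_true(os$all_z_ge_3)
  expect_equal(os$retained, c(10, 11, 12, 13))

  expect_length(detect_outliers(c(10, 11, 12, 13, 14))$outlier_idx, 0)

  # the relaxed 3 x IQR variant un-flags 18 that 1.5 x IQR catches
  expect_equal(detect_outliers(c(10, 11, 12, 13, 18), factor = 1.5)$outlier_values, 18)
  expect_length(detect_outliers(c(10, 11, 12, 13, 18), factor = 3)$outlier_idx, 0)

  expect_error(detect_outliers(c(1, 2, 3)), "at least 4")
})

test_that("outlier flagging matches brute force over enumerated small sets", {
  set.seed(42)
  for (n in 4:8) {
    for (rep in 1:25) {
      x <- sample(1:30, n, replace = TRUE)
      os <- detect_outliers(x)
      # independent oracle: explicit fences from the (n-1)q quantile rule
      q1 <- quantile_oracle(x, 0.25)
      q3 <- quantile_oracle(x, 0.75)
      lo <- q1 - 1.5 * (q3 - q1)
      hi <- q3 + 1.5 * (q3 - q1)
      expect_identical(sort(os$outlier_idx), which(x < lo | x > hi))
    }
  }
})

test_that("flagging is invariant to ordering and affine rescaling", {
  set.seed(7)
  x <- c(rlnorm(12, log(100), 0.3), 500)
  base <- sort(detect_outliers(x)$outlier_values)
  expect_equal(sort(detect_outliers(rev(x))$outlier_values), base)
  os2 <- detect_outliers(3 * x + 17)
  expect_equal(sort(os2$outlier_values), 3 * base + 17)
  expect_equal(os2$fences, 3 * detect_outliers(x)$fences + 17)
})

test_that("group summaries use the SEM convention", {
  s <- summarize_modulus(c(100, 100, 100))
  expect_equal(s$mean, 100); expect_equal(s$sem, 0)
  s2 <- summarize_modulus(c(90, 110))
  expect_equal(s2$mean, 100); expect_equal(s2$sem, 10)
  expect_error(summarize_modulus(100), "at least 2")
  # simulated group mean is consistent with the generator
  x <- draw_cell_moduli(113, 0.3, 50, seed = 9)
  s3 <- summarize_modulus(x)
  gen_mean <- 113 * exp(0.3^2 / 2)       # log-normal mean
  expect_lt(abs(s3$mean - gen_mean), 2 * s3$sem)
})

test_that("two-sample comparisons behave at the degenerate and extreme ends", {
  same <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_false(same$significant)
  far <- compare_groups(c(1, 2, 3), c(101, 102, 103))
  expect_lt(far$p, 0.001)
  expect_true(far$significant)
  # zero variance, different means
  expect_equal(compare_groups(c(5, 5), c(9, 9))$p, 0)
  expect_error(compare_groups(c(1, 2, 3), c(1, 2), alpha = 1.2))
})

test_that("the Welch p value matches a permutation oracle", {
  set.seed(3)
  worst <- 0
  for (rep in 1:5) {
    a <- rnorm(8, 100, 12); b <- rnorm(9, 108, 18)
    p_w <- compare_groups(a, b)$p
    # permutation oracle on the Welch statistic
    pool <- c(a, b); na <- length(a)
    tstat <- function(ia) {
      x <- pool[ia]; y <- pool[-ia]
      (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
    }
    t0 <- abs(tstat(seq_len(na)))
    tp <- replicate(4000, abs(tstat(sample(length(pool), na))))
    p_perm <- mean(tp >= t0)
    worst <- max(worst, abs(p_w - p_perm))
  }
  expect_lt(worst, 0.06)
})

test_that("the indentation-order trend isolates the first-indentation step", {
  p <- synth_curve_params(E_true = 100, noise_sd = 0, model = "paraboloid")
  mk_cell <- function(seed, id)
    lapply(simulate_cell(100, p, n_curves = 6, first_shift_factor = 0.7,
                         seed = seed, cell_id = id),
           correct_and_fit, model = contact_model("paraboloid"))
  cells <- lapply(1:3, function(i) assess_cell(mk_cell(i, paste0("c", i)),
                                               min_post_qc = 1, min_averaged = 1))
  tr <- indentation_trend(cells, max_index = 6)
  expect_equal(tr$index, 2:6)
  expect_equal(which.max(tr$mean_abs_dE), 1L)      # i = 2 step dominates
  expect_gt(tr$mean_dE[1], 0)                      # softer first curve
  expect_equal(tr$mean_abs_dE[-1], rep(0, 4), tolerance = 1e-6)

  # no shift, noiseless: all steps are zero
  cells1 <- lapply(4:5, function(i)
    assess_cell(lapply(simulate_cell(100, p, n_curves = 4,
                                     first_shift_factor = 1, seed = i,
                                     cell_id = paste0("d", i)),
                       correct_and_fit, model = contact_model("paraboloid")),
                min_post_qc = 1, min_averaged = 1))
  tr1 <- indentation_trend(cells1, max_index = 4)
  expect_equal(tr1$mean_dE, rep(0, 3), tolerance = 1e-6)

  # missing indices are skipped pairwise
  cr <- cells[[1]]
  cr$E_by_index <- cr$E_by_index[c("1", "2", "4", "5")]
  tr2 <- indentation_trend(list(cr), max_index = 5)
  expect_equal(tr2$n_pairs, c(1L, 0L, 0L, 1L))
})

test_that("population_summary reports both pre- and post-outlier cell counts", {
  df <- data.frame(cell_id = sprintf("c%02d", 1:12),
                   group = rep(c("A", "B"), each = 6),
                   included = TRUE, reason = "",
                   n_qc = 15L, n_avg = 14L,
                   E_cell_Pa = c(100, 101, 99, 102, 98, 500,
                                 150, 151, 149, 152, 148, 150),
                   E_first_Pa = NA_real_, area_um2 = NA_real_)
  pop <- population_summary(df)
  ga <- pop$groups[pop$groups$group == "A", ]
  expect_equal(ga$n_input, 6L)
  expect_equal(ga$n_outliers, 1L)
  expect_equal(ga$n_retained, 5L)
  expect_equal(ga$mean_Pa, 100)
  expect_equal(pop$outliers$E_Pa, 500)
  expect_true(pop$comparisons$significant)
})
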