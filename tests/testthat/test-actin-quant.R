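test_that("rolling-ball background subtraction removes smooth backgrounds only", {
  const <- actin_image(matrix(50, 64, 64), 100e-9)
  expect_lt(max(subtract_background(const, 20)$pixels), 1e-9)

  # single bright spot on a constant background survives intact
  px <- matrix(50, 64, 64); px[30, 30:32] <- 200
  out <- subtract_background(actin_image(px, 100e-9), 20)$pixels
  expect_gt(out[30, 31], 0.9 * 150)
  expect_lt(max(out[1:10, 1:10]), 1e-9)

  # linear gradient + filament: the filament peak is preserved within 10%
  g <- outer(seq(0, 30, length.out = 64), rep(1, 64))
  g[32, 20:45] <- g[32, 20:45] + 80
  out2 <- subtract_background(actin_image(g, 100e-9), 20)$pixels
  expect_gt(max(out2[32, 20:45]), 0.9 * 80)
  expect_lt(stats::median(out2[10, ]), 8)

  expect_error(subtract_background(actin_image(matrix(1, 16, 16), 100e-9), 20),
               "larger than the image")
})

test_that("smoothing conserves intensity and reduces noise as expected", {
  px <- matrix(rnorm(96 * 96, 100, 10), 96, 96)
  img <- actin_image(px, 100e-9)
  expect_identical(smooth_image(img, 0)$pixels, px)
  # delta image: blur sums to the input total
  d <- matrix(0, 33, 33); d[17, 17] <- 1
  sm <- smooth_image(actin_image(d, 100e-9), 1.5)$pixels
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_lt(max(sm), 1)
  # noise SD reduced by ~ 1 / (2 sqrt(pi) sigma) on a pure-noise image
  sm2 <- smooth_image(img, 1)$pixels
  inner <- sm2[10:86, 10:86]
  expect_equal(sd(inner) / 10, 1 / (2 * sqrt(pi)), tolerance = 0.2)
})

test_that("thresholding recovers two-level images and honors manual overrides", {
  px <- matrix(0, 40, 40); px[10:20, 10:20] <- 100
  img <- actin_image(px, 100e-9)
  bz <- binarize(img, "otsu")
  expect_identical(bz$mask, px > 50)
  bz2 <- binarize(img, 42)
  expect_identical(bz2$mask, px > 42)
  expect_equal(bz2$threshold, 42)
  expect_error(binarize(actin_image(matrix(5, 10, 10), 100e-9), "otsu"),
               "constant")
  expect_error(binarize(img, "magic"), "unknown")
})

test_that("skeleton lengths follow the step-sum convention exactly", {
  # horizontal 10 x 1 bar at 100 nm/px: 9 unit steps = 0.9 um
  mask <- matrix(FALSE, 20, 20); mask[10, 5:14] <- TRUE
  rec <- skeletonize_and_measure(mask, 100e-9)
  expect_length(rec, 1L)
  expect_equal(rec[[1]]$length, 0.9e-6)
  # diagonal 10-px chain: 9 sqrt(2) steps
  m2 <- matrix(FALSE, 20, 20); for (i in 0:9) m2[5 + i, 5 + i] <- TRUE
  expect_equal(skeletonize_and_measure(m2, 100e-9)[[1]]$length,
               9 * sqrt(2) * 1e-7)
  # solid square thins to something far shorter than its perimeter
  m3 <- matrix(FALSE, 30, 30); m3[10:19, 10:19] <- TRUE
  lens <- vapply(skeletonize_and_measure(m3, 100e-9), `[[`, numeric(1), "length")
  expect_lt(sum(lens), 0.3 * (36 * 1e-7))
  # two disjoint bars give two records; an empty mask gives none
  m4 <- matrix(FALSE, 20, 20); m4[5, 2:8] <- TRUE; m4[15, 2:8] <- TRUE
  expect_length(skeletonize_and_measure(m4, 100e-9), 2L)
  expect_length(skeletonize_and_measure(matrix(FALSE, 5, 5), 100e-9), 0L)
})

test_that("cortex removal drops ring skeletons and keeps interior filaments", {
  n <- 81
  centre <- 41
  xs <- seq_len(n) - centre
  rr <- sqrt(outer(xs^2, rep(1, n)) + outer(rep(1, n), xs^2))
  cell_mask <- rr <= 35
  # ring skeleton tracing the perimeter + a central bar + a bar touching the band
  ring <- abs(rr - 33) < 0.7
  bar <- matrix(FALSE, n, n); bar[centre, (centre - 10):(centre + 10)] <- TRUE
  touch <- matrix(FALSE, n, n); touch[centre + 3, centre:(centre + 29)] <- TRUE
  recs <- c(skeletonize_and_measure(ring, 100e-9, extend_tips = FALSE),
            skeletonize_and_measure(bar, 100e-9, extend_tips = FALSE),
            skeletonize_and_measure(touch, 100e-9, extend_tips = FALSE))
  out <- remove_cortex(recs, cell_mask, 100e-9)
  lens <- sapply(out$records, function(r) r$length)
  expect_equal(length(out$removed), 1L)                 # the ring
  expect_gt(out$removed[[1]]$length, 15e-6)
  expect_length(lens, 2L)
  # central bar has zero overlap; the touching bar's overlap is the in-band
  # fraction computed independently from the geometry
  ovs <- sapply(out$records, function(r) r$cortex_overlap)
  expect_equal(min(ovs), 0)
  band_px <- 5
  tpx <- which(touch, arr.ind = TRUE)
  d_bound <- 35 - rr[touch]
  expected <- mean(d_bound <= band_px + 0.5)
  expect_equal(max(ovs), expected, tolerance = 0.15)
  expect_lt(max(ovs), 0.8)                              # retained
})

test_that("merged cortex skeletons are split, not retained wholesale", {
  n <- 81; centre <- 41
  xs <- seq_len(n) - centre
  rr <- sqrt(outer(xs^2, rep(1, n)) + outer(rep(1, n), xs^2))
  cell_mask <- rr <= 35
  merged <- abs(rr - 33) < 0.7                       # ring ...
  merged[centre, 10:(centre + 5)] <- TRUE            # ... plus a bar crossing it
  recs <- skeletonize_and_measure(merged, 100e-9, extend_tips = FALSE)
  out <- remove_cortex(recs, cell_mask, 100e-9)
  kept <- sapply(out$records, function(r) r$length)
  expect_gte(length(out$removed), 1L)
  # the retained cytosolic branch is bar-sized, not ring-sized
  expect_lt(max(kept), 5e-6)
  expect_gt(max(kept), 1.5e-6)
})

test_that("the 250 nm filter and summaries match hand computation", {
  recs <- lapply(c(0.2e-6, 0.3e-6, 1.0e-6), function(L)
    list(id = 1, pixels = cbind(1, 1), length = L))
  fs <- filter_and_summarize(recs)
  expect_equal(fs$total_length, 1.3e-6)
  expect_equal(fs$mean_length, 0.65e-6)
  expect_equal(fs$n_structures, 2L)
  all_small <- filter_and_summarize(lapply(c(0.1e-6, 0.2e-6), function(L)
    list(id = 1, pixels = cbind(1, 1), length = L)))
  expect_equal(all_small$total_length, 0)
  expect_equal(all_small$n_structures, 0L)
  empty <- filter_and_summarize(list())
  expect_equal(empty$total_length, 0)
})

test_that("a ring-only scene yields zero cytosolic length end to end", {
  p <- actin_synth_params(n_filaments = 0L, n_puncta = 0L, noise_sd = 0)
  sim <- simulate_actin_image(p, seed = 1)
  m <- quantify_actin(sim$image)
  expect_equal(m$total_length_um, 0)
  expect_gte(m$n_cortex_removed, 1L)
})

test_that("measured totals are rotation-tolerant and monotone in content", {
  # rotation: the same straight filament horizontal vs diagonal through the
  # full pipeline (blur, threshold, thinning, tip extension)
  mk <- function(diagonal) {
    px <- matrix(0, 96, 96)
    if (diagonal) for (i in 0:12) px[42 + i, 42 + i] <- 80
    else px[48, 40:52] <- 80
    blur <- afmcell:::gaussian_blur(px, 1.2) + 10
    img <- actin_image(blur, 100e-9)
    work <- smooth_image(subtract_background(img, 20), 1)
    recs <- skeletonize_and_measure(binarize(work, 7)$mask, 100e-9,
                                    intensity = work$pixels)
    sum(sapply(recs, `[[`, "length"))
  }
  h <- mk(FALSE); d <- mk(TRUE)
  expect_equal(d / (12 * sqrt(2)), h / 12, tolerance = 0.1)

  # monotonicity: adding a filament never decreases the measured total
  pa <- actin_synth_params(n_filaments = 4L, noise_sd = 0)
  pb <- actin_synth_params(n_filaments = 5L, noise_sd = 0)
  ta <- quantify_actin(simulate_actin_image(pa, seed = 9)$image)$total_length_um
  tb <- quantify_actin(simulate_actin_image(pb, seed = 9)$image)$total_length_um
  expect_gte(tb, ta - 1e-9)
})

test_that("per-cell totals track ground truth across a wide range", {
  truth <- c(); meas <- c()
  counts <- c(3L, 6L, 10L, 14L, 18L, 22L, 26L, 30L)
  for (i in seq_along(counts)) {
    p <- actin_synth_params(n_filaments = counts[i])
    sim <- simulate_actin_image(p, seed = 20 + i)
    truth <- c(truth, sim$truth$total_length_um)
    meas <- c(meas, quantify_actin(sim$image)$total_length_um)
  }
  expect_gte(cor(truth, meas, method = "spearman"), 0.9)
  expect_lt(median(abs(meas / truth - 1)), 0.15)
})
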