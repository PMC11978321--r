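# shared fixtures: built in code, no stored data

# fast paraboloid world for cohort-scale tests (coarser piezo sampling to
# keep the suite quick; accuracy checks use the default 5 nm grid)
fast_curve_params <- function(E_true = 113, ...) {
  synth_curve_params(E_true = E_true, sample_spacing = 10e-9,
                     model = "paraboloid", ...)
}

fast_config <- function(...) {
  run_config(model = "paraboloid", ...)
}

# minimal hand-built curve_fit_result for cell-protocol oracles
make_fit <- function(E, idx, flags = character(0), cell = "c1",
                     group = "A") {
  structure(list(E = E, contact_point = 2.45e-6, max_indentation = 1e-6,
                 rms_residual = 1e-12, n_fit_points = 300L,
                 qc = list(flags = flags, baseline_span = 1e-6,
                           noise_sd = 1e-11, depth_ratio = NA_real_),
                 cell_id = cell, curve_index = as.integer(idx),
                 group = group),
            class = "curve_fit_result")
}

# independent quantile oracle: linear interpolation at (n - 1) * q
quantile_oracle <- function(x, q) {
  x <- sort(x)
  pos <- (length(x) - 1) * q
  lo <- floor(pos)
  frac <- pos - lo
  x[lo + 1] + frac * (ifelse(lo + 2 <= length(x), x[pmin(lo + 2, length(x))], x[lo + 1]) - x[lo + 1])
}

# independent Sneddon-sphere oracle: bisection on the contact radius
sneddon_force_oracle <- function(delta, R, nu, E) {
  a_of <- function(a) a / 2 * log((R + a) / (R - a))
  lo <- 0; hi <- R * (1 - 1e-12)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (a_of(mid) < delta) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  E / (1 - nu^2) * ((a^2 + R^2) / 2 * log((R + a) / (R - a)) - a * R)
}
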