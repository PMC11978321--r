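#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with defaults equal to the
#' protocol's stated values: 1 nN set point handling, 500 nm minimum
#' baseline, 11 curves post-QC / 10 averaged inclusion rules, 1.5 x IQR
#' fences, Welch test at alpha 0.05, nu = 0.5, R = 10 um, rolling-ball
#' radius 20 px, 250 nm minimum skeleton length.
#'
#' @param model contact model kind ("sneddon_sphere" or "paraboloid").
#' @param nu Poisson ratio.
#' @param R probe radius, m.
#' @param min_baseline_span minimum flat baseline, m.
#' @param fit_slope remove linear baseline tilt too.
#' @param contact_q noise multiple for contact seeding.
#' @param pinch_depth,pinch_width pinch QC thresholds (N, m).
#' @param residual_tol bad_residual threshold as fraction of set point.
#' @param E_bounds fit bounds for E, Pa.
#' @param min_curves_post_qc,min_curves_averaged cell inclusion rules.
#' @param first_only analyze only first indentations.
#' @param outlier_factor Tukey fence multiplier.
#' @param test_kind "welch" or "pooled".
#' @param alpha significance level, in (0, 1).
#' @param rolling_ball_radius background-removal radius, px.
#' @param smooth_sigma image smoothing sigma, px.
#' @param threshold_method "background" (default), "otsu", "multiotsu", or a
#'   manual numeric threshold; see \code{\link{binarize}}.
#' @param cortex_band cortex exclusion band width, m.
#' @param cortex_overlap overlap fraction above which a skeleton is cortical.
#' @param min_skeleton_length minimum retained skeleton length, m.
#' @param seed integer seed recorded in provenance.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(model = "sneddon_sphere", nu = 0.5, R = 10e-6,
                       min_baseline_span = 500e-9, fit_slope = FALSE,
                       contact_q = 3,
                       pinch_depth = 50e-12, pinch_width = 50e-9,
                       residual_tol = 0.05, E_bounds = c(1, 1e6),
                       min_curves_post_qc = 11L, min_curves_averaged = 10L,
                       first_only = FALSE,
                       outlier_factor = 1.5, test_kind = "welch", alpha = 0.05,
                       rolling_ball_radius = 20L, smooth_sigma = 1,
                       threshold_method = "background",
                       cortex_band = 0.5e-6, cortex_overlap = 0.8,
                       min_skeleton_length = 250e-9,
                       seed = 1L) {
  stopifnot(model %in% c("sneddon_sphere", "paraboloid"),
            nu > 0, nu <= 0.5, R > 0, min_baseline_span > 0,
            pinch_depth > 0, pinch_width > 0, residual_tol > 0,
            length(E_bounds) == 2L, E_bounds[1L] < E_bounds[2L],
            min_curves_post_qc >= 1L, min_curves_averaged >= 1L,
            outlier_factor > 0, test_kind %in% c("welch", "pooled"),
            rolling_ball_radius >= 1L, smooth_sigma >= 0,
            cortex_band > 0, cortex_overlap > 0, cortex_overlap <= 1,
            min_skeleton_length >= 0)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("alpha must be a single value in (0, 1)")
  structure(list(model = model, nu = nu, R = R,
                 min_baseline_span = min_baseline_span, fit_slope = fit_slope,
                 contact_q = contact_q, pinch_depth = pinch_depth,
                 pinch_width = pinch_width, residual_tol = residual_tol,
                 E_bounds = E_bounds,
                 min_curves_post_qc = as.integer(min_curves_post_qc),
                 min_curves_averaged = as.integer(min_curves_averaged),
                 first_only = first_only,
                 outlier_factor = outlier_factor, test_kind = test_kind,
                 alpha = alpha,
                 rolling_ball_radius = as.integer(rolling_ball_radius),
                 smooth_sigma = smooth_sigma,
                 threshold_method = threshold_method,
                 cortex_band = cortex_band, cortex_overlap = cortex_overlap,
                 min_skeleton_length = min_skeleton_length,
                 seed = as.integer(seed)),
            class = "run_config")
}
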