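#' Parameters for a synthetic measurement cohort
#'
#' Describes one or more cell groups whose per-cell Young's moduli are drawn
#' log-normally (moduli are positive and right-skewed in measured cohorts)
#' around a group median, with occasional high-modulus outlier cells and
#' per-curve acquisition artifacts.
#'
#' @param groups list of group descriptors, each a list/vector with elements
#'   \code{label}, \code{median_E} (Pa), \code{log_sd} (SD of log-modulus),
#'   \code{n_cells}.
#' @param curves_per_cell repeat indentations per cell (default 15).
#' @param first_shift_factor multiplicative modulus shift applied to curve #1
#'   of every cell (default 0.7; the first indentation reads softer before the
#'   probe has pushed the cell into its settled position).
#' @param outlier_fraction probability that a cell is an outlier.
#' @param outlier_multiplier modulus multiplier for outlier cells (> 1).
#' @param artifact_rates named numeric vector/list with per-curve probabilities
#'   \code{short_baseline} and \code{pinch}.
#' @param curve_params a \code{\link{synth_curve_params}} template (its
#'   \code{E_true} is overridden); default uses the standard acquisition.
#' @param seed master integer seed.
#' @return Object of class \code{cohort_params}.
#' @export
cohort_params <- function(groups,
                          curves_per_cell = 15L,
                          first_shift_factor = 0.7,
                          outlier_fraction = 0,
                          outlier_multiplier = 5,
                          artifact_rates = c(short_baseline = 0, pinch = 0),
                          curve_params = NULL,
                          seed = 1L) {
  stopifnot(length(groups) >= 1L)
  groups <- lapply(groups, function(g) {
    g <- as.list(g)
    stopifnot(all(c("label", "median_E", "log_sd", "n_cells") %in% names(g)))
    g$median_E <- as.numeric(g$median_E); g$log_sd <- as.numeric(g$log_sd)
    g$n_cells <- as.integer(g$n_cells)
    stopifnot(g$median_E > 0, g$log_sd >= 0, g$n_cells >= 1L)
    g
  })
  ar <- as.list(artifact_rates)
  stopifnot(all(unlist(ar) >= 0), all(unlist(ar) <= 1),
            outlier_fraction >= 0, outlier_fraction <= 1,
            outlier_multiplier > 1, first_shift_factor > 0)
  if (is.null(curve_params)) curve_params <- synth_curve_params(E_true = 100)
  structure(list(groups = groups, curves_per_cell = as.integer(curves_per_cell),
                 first_shift_factor = first_shift_factor,
                 outlier_fraction = outlier_fraction,
                 outlier_multiplier = outlier_multiplier,
                 artifact_rates = ar, curve_params = curve_params,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Draw per-cell true moduli for one group
#'
#' Log-normal draws with \code{median_E} as the distribution median
#' (\code{meanlog = log(median_E)}, \code{sdlog = log_sd}), so all draws are
#' positive and the empirical median converges to \code{median_E}.
#'
#' @param median_E group median modulus, Pa.
#' @param log_sd SD of the log-modulus.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return numeric vector of moduli (Pa).
#' @export
draw_cell_moduli <- function(median_E, log_sd, n_cells, seed = 1L) {
  set.seed(as.integer(seed))
  stats::rlnorm(n_cells, meanlog = log(median_E), sdlog = log_sd)
}

#' Simulate a full measurement cohort
#'
#' Generates every force curve for every cell of every group, plus a
#' ground-truth table. Outlier cells get their modulus multiplied by
#' \code{outlier_multiplier}; per-curve artifacts (short baseline, membrane
#' pinch) are injected at the configured rates. All randomness flows from the
#' single master seed through per-cell substreams, so any subset is
#' reproducible.
#'
#' @param params a \code{\link{cohort_params}}.
#' @return A \code{curve_bundle}: list with \code{curves} (flat list of
#'   \code{\link{force_curve}}), \code{cells} (data.frame of per-cell
#'   metadata), \code{truth} (data.frame cell_id, group, E_true_Pa, outlier,
#'   artifacts) and \code{provenance}.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n_groups <- length(p$groups)
  group_seeds <- substream_seeds(p$seed, n_groups * 3L)

  curves <- list()
  truth <- list()
  cells <- list()
  # measurability floor: cells whose softest curve (including the curve-1
  # shift) cannot reach the set point within the piezo travel are not
  # acquirable and are redrawn -- the instrument's range truncates the
  # soft tail of the cohort
  E_floor <- feasible_E_floor(p$curve_params) /
    min(p$first_shift_factor, 1) * 1.02

  for (gi in seq_len(n_groups)) {
    g <- p$groups[[gi]]
    E_cells <- draw_cell_moduli(g$median_E, g$log_sd, g$n_cells,
                                seed = group_seeds[3L * gi - 2L])
    redraw_seeds <- substream_seeds(group_seeds[3L * gi - 2L] + 1L, 100L)
    attempt <- 1L
    while (any(E_cells < E_floor) && attempt <= 100L) {
      idx <- which(E_cells < E_floor)
      E_cells[idx] <- draw_cell_moduli(g$median_E, g$log_sd, length(idx),
                                       seed = redraw_seeds[attempt])
      attempt <- attempt + 1L
    }
    if (any(E_cells < E_floor))
      stop("group '", g$label, "': median_E too soft for the acquisition ",
           "range (measurability floor ", signif(E_floor, 3), " Pa)")
    # plant the stated fraction exactly (random positions): Bernoulli counts
    # occasionally exceed the ~25% masking breakdown of Tukey fences, which
    # would test the method's known failure mode rather than the pipeline
    set.seed(group_seeds[3L * gi - 1L])
    n_out <- round(p$outlier_fraction * g$n_cells)
    is_outlier <- rep(FALSE, g$n_cells)
    if (n_out > 0L)
      is_outlier[sample.int(g$n_cells, n_out)] <- TRUE
    E_cells[is_outlier] <- E_cells[is_outlier] * p$outlier_multiplier
    cell_seeds <- substream_seeds(group_seeds[3L * gi], g$n_cells * 2L)

    for (ci in seq_len(g$n_cells)) {
      cell_id <- sprintf("%s_c%03d", g$label, ci)
      # per-curve artifact draws
      set.seed(cell_seeds[2L * ci - 1L])
      sb <- stats::runif(p$curves_per_cell) < p$artifact_rates$short_baseline
      pn <- stats::runif(p$curves_per_cell) < p$artifact_rates$pinch
      artifact <- lapply(seq_len(p$curves_per_cell), function(i) {
        if (!sb[i] && !pn[i]) return(NULL)
        list(short_baseline = sb[i],
             pinch = if (pn[i]) list(depth = 100e-12, width = 30e-9,
                                     position = 400e-9) else NULL)
      })
      cc <- simulate_cell(E_cells[ci], p$curve_params,
                          n_curves = p$curves_per_cell,
                          first_shift_factor = p$first_shift_factor,
                          seed = cell_seeds[2L * ci], cell_id = cell_id,
                          group = g$label, artifact = artifact)
      curves <- c(curves, cc)
      art_lab <- paste(c(if (any(sb)) "short_baseline", if (any(pn)) "pinch"),
                       collapse = "+")
      truth[[cell_id]] <- data.frame(cell_id = cell_id, group = g$label,
                                     E_true_Pa = E_cells[ci],
                                     outlier = is_outlier[ci],
                                     artifacts = if (nzchar(art_lab)) art_lab else "none",
                                     stringsAsFactors = FALSE)
      cells[[cell_id]] <- data.frame(cell_id = cell_id, group = g$label,
                                     area_um2 = NA_real_,
                                     moved_or_morphology_excluded = FALSE,
                                     stringsAsFactors = FALSE)
    }
  }
  structure(list(curves = curves,
                 cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 provenance = list(generator = "simulate_cohort",
                                   seed = p$seed,
                                   format_version = "1.0")),
            class = "curve_bundle")
}

#' @export
print.curve_bundle <- function(x, ...) {
  cat(sprintf("<curve_bundle> %d curves, %d cells, groups: %s\n",
              length(x$curves), nrow(x$cells),
              paste(unique(x$cells$group), collapse = ", ")))
  invisible(x)
}
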