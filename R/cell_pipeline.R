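#' Apply the per-cell inclusion protocol
#'
#' Order of operations is fixed:
#' \enumerate{
#'   \item drop curves failing QC (\code{\link{qc_pass}});
#'   \item exclude the cell if fewer than \code{min_post_qc} (default 11)
#'     curves survive;
#'   \item drop the curve with index 1 (the first indentation) if it survived;
#'   \item exclude the cell if fewer than \code{min_averaged} (default 10)
#'     curves remain;
#'   \item the cell modulus is the arithmetic mean of the remaining fits.
#' }
#' Cells flagged \code{moved_or_morphology_excluded} in the metadata are
#' excluded regardless (these removals are optical-inspection input, not
#' computed). With 15 curves this yields 10-14 averaged curves per included
#' cell. In \code{first_only} mode the cell modulus is instead curve #1's
#' fit (the robustness check that uses only first indentations).
#'
#' @param fits list of \code{curve_fit_result} from one cell, carrying
#'   1-based curve indices.
#' @param metadata optional list/row with \code{group}, \code{area_um2},
#'   \code{moved_or_morphology_excluded}.
#' @param min_post_qc minimum QC survivors for inclusion (default 11).
#' @param min_averaged minimum curves entering the average (default 10).
#' @param first_only analyze only the first indentation (default FALSE).
#' @return Object of class \code{cell_result}: \code{cell_id}, \code{group},
#'   \code{included}, \code{reason}, \code{n_curves_passing_qc},
#'   \code{n_curves_averaged}, \code{E_cell}, \code{E_first},
#'   \code{E_by_index} (named vector of QC-passing fits for trend analysis),
#'   \code{area_um2}.
#' @export
assess_cell <- function(fits, metadata = NULL, min_post_qc = 11L,
                        min_averaged = 10L, first_only = FALSE) {
  if (length(fits) == 0L) stop("empty fit list")
  stopifnot(all(vapply(fits, inherits, logical(1), "curve_fit_result")))
  idx <- vapply(fits, `[[`, integer(1), "curve_index")
  if (anyDuplicated(idx)) stop("duplicate curve indices within one cell")
  cell_id <- fits[[1L]]$cell_id
  group <- if (!is.null(metadata$group)) metadata$group else fits[[1L]]$group
  area <- if (!is.null(metadata$area_um2)) metadata$area_um2 else NA_real_
  moved <- isTRUE(metadata$moved_or_morphology_excluded)

  E_all <- vapply(fits, `[[`, numeric(1), "E")
  pass <- vapply(fits, qc_pass, logical(1)) & is.finite(E_all)
  E_first <- if (any(idx == 1L)) E_all[idx == 1L] else NA_real_
  E_pass <- E_all[pass]
  names(E_pass) <- idx[pass]
  n_qc <- sum(pass)

  finish <- function(included, reason, n_avg, E_cell) {
    structure(list(cell_id = cell_id, group = group, included = included,
                   reason = reason, n_curves_passing_qc = n_qc,
                   n_curves_averaged = n_avg, E_cell = E_cell,
                   E_first = E_first,
                   E_by_index = E_pass[order(as.integer(names(E_pass)))],
                   area_um2 = area,
                   moved_or_morphology_excluded = moved),
              class = "cell_result")
  }

  if (moved)
    return(finish(FALSE, "moved or morphology change (optical inspection)",
                  0L, NA_real_))

  if (first_only) {
    ok <- any(idx == 1L) && pass[idx == 1L]
    if (!ok) return(finish(FALSE, "first indentation missing or failed QC",
                           0L, NA_real_))
    return(finish(TRUE, "", 1L, E_first))
  }

  if (n_qc < min_post_qc)
    return(finish(FALSE,
                  sprintf("fewer than %d curves after QC", min_post_qc),
                  0L, NA_real_))
  keep <- pass & idx >= 2L          # first indentation removed
  n_avg <- sum(keep)
  if (n_avg < min_averaged)
    return(finish(FALSE,
                  sprintf("fewer than %d curves after first-indentation removal",
                          min_averaged),
                  0L, NA_real_))
  finish(TRUE, "", n_avg, mean(E_all[keep]))
}

#' Fit and assess every cell of a bundle
#'
#' Runs \code{\link{correct_and_fit}} on every curve and
#' \code{\link{assess_cell}} on every cell of a \code{curve_bundle}.
#' Deterministic given its inputs.
#'
#' @param bundle a \code{curve_bundle} (from \code{\link{simulate_cohort}} or
#'   \code{\link{read_bundle_tsv}} / \code{\link{read_bundle_h5}}).
#' @param model a \code{\link{contact_model}}; defaults to the Sneddon sphere
#'   with the bundle's probe radius.
#' @param config a \code{\link{run_config}} supplying QC and inclusion
#'   thresholds.
#' @return list with \code{fits} (all \code{curve_fit_result}s) and
#'   \code{cells} (list of \code{cell_result}).
#' @export
run_bundle <- function(bundle, model = NULL, config = run_config()) {
  stopifnot(inherits(bundle, "curve_bundle"))
  if (is.null(model))
    model <- contact_model(config$model, R = bundle$curves[[1L]]$R,
                           nu = config$nu)
  fits <- lapply(bundle$curves, function(cu) {
    correct_and_fit(cu, model = model,
                    min_span = config$min_baseline_span,
                    fit_slope = config$fit_slope, q = config$contact_q,
                    residual_tol = config$residual_tol,
                    E_bounds = config$E_bounds,
                    pinch_opts = list(drop_threshold = config$pinch_depth,
                                      window_width = config$pinch_width))
  })
  by_cell <- split(fits, vapply(fits, `[[`, character(1), "cell_id"))
  meta <- bundle$cells
  cells <- lapply(names(by_cell), function(id) {
    md <- if (!is.null(meta) && id %in% meta$cell_id)
      as.list(meta[meta$cell_id == id, , drop = FALSE]) else NULL
    assess_cell(by_cell[[id]], metadata = md,
                min_post_qc = config$min_curves_post_qc,
                min_averaged = config$min_curves_averaged,
                first_only = config$first_only)
  })
  names(cells) <- names(by_cell)
  list(fits = fits, cells = cells)
}

#' Per-cell results as a data.frame
#'
#' @param cells list of \code{cell_result}.
#' @return data.frame with one row per cell (cell_id, group, included,
#'   reason, n_qc, n_avg, E_cell_Pa, E_first_Pa, area_um2).
#' @export
cell_table <- function(cells) {
  do.call(rbind, c(lapply(cells, function(cr) {
    data.frame(cell_id = cr$cell_id, group = cr$group,
               included = cr$included, reason = cr$reason,
               n_qc = cr$n_curves_passing_qc, n_avg = cr$n_curves_averaged,
               E_cell_Pa = cr$E_cell, E_first_Pa = cr$E_first,
               area_um2 = cr$area_um2, stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}

#' Per-curve fit results as a data.frame
#'
#' @param fits list of \code{curve_fit_result}.
#' @return data.frame (cell_id, curve_index, E_Pa, contact_point_m,
#'   max_indentation_m, rms_residual_N, qc_flags).
#' @export
fit_table <- function(fits) {
  do.call(rbind, c(lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id, curve_index = f$curve_index,
               E_Pa = f$E, contact_point_m = f$contact_point,
               max_indentation_m = f$max_indentation,
               rms_residual_N = f$rms_residual,
               qc_flags = paste(f$qc$flags, collapse = "+"),
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
}
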