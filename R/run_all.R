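#' End-to-end analysis of a curve bundle
#'
#' fit -> aggregate -> stats in one call: fits every curve, applies the
#' per-cell protocol, then outlier handling, group summaries, pairwise
#' comparisons and the indentation-order trend. When \code{out_dir} is given
#' the tables are written as CSV plus a JSON run log carrying the full
#' configuration and seed; output is deterministic (byte-identical CSVs on
#' re-run with the same inputs).
#'
#' @param bundle a \code{curve_bundle}.
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional output directory (created if missing).
#' @return list: \code{fits} (data.frame), \code{cells} (data.frame),
#'   \code{groups}, \code{outliers}, \code{comparisons}, \code{trend}
#'   (data.frames), \code{log} (list).
#' @export
run_afm_analysis <- function(bundle, config = run_config(), out_dir = NULL) {
  rb <- run_bundle(bundle, config = config)
  fit_df <- fit_table(rb$fits)
  cell_df <- cell_table(rb$cells)
  pop <- population_summary(cell_df, factor = config$outlier_factor,
                            kind = config$test_kind, alpha = config$alpha)
  trend <- indentation_trend(rb$cells)
  log <- list(config = unclass(config),
              n_curves = length(bundle$curves),
              n_cells = nrow(cell_df),
              n_included = sum(cell_df$included),
              dispositions = table(ifelse(cell_df$included, "included",
                                          cell_df$reason)))
  log$dispositions <- as.list(log$dispositions)
  res <- list(fits = fit_df, cells = cell_df, groups = pop$groups,
              outliers = pop$outliers, comparisons = pop$comparisons,
              trend = trend, log = log)
  if (!is.null(out_dir)) write_analysis_outputs(res, out_dir)
  res
}

# numbers serialized at full precision so identical inputs give identical bytes
write_csv_det <- function(df, path) {
  if (is.null(df)) {
    writeLines("", path)
    return(invisible(path))
  }
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

write_analysis_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_det(res$fits, file.path(out_dir, "curve_fits.csv"))
  write_csv_det(res$cells, file.path(out_dir, "cells.csv"))
  write_csv_det(res$groups, file.path(out_dir, "group_summary.csv"))
  write_csv_det(res$outliers, file.path(out_dir, "outliers.csv"))
  write_csv_det(res$comparisons, file.path(out_dir, "comparisons.csv"))
  write_csv_det(res$trend, file.path(out_dir, "indentation_trend.csv"))
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
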