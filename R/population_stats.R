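#' Tukey-fence outlier detection with post-hoc z validation
#'
#' Quartiles use linear interpolation of the order statistics at positions
#' \code{(n - 1) * q} (R quantile type 7); values outside
#' \code{[Q1 - factor * IQR, Q3 + factor * IQR]} are flagged. Each flagged
#' value's z score is computed against the mean and SD of the *other* values
#' (leave-one-out): with the candidate included, the largest attainable |z|
#' is \code{(n - 1) / sqrt(n)}, so an included-sample z test could never
#' validate an outlier in a small cohort. The z scores are reported for
#' validation only and never un-flag a value. \code{factor = 3} gives the
#' relaxed variant.
#'
#' @param values numeric vector of per-cell moduli (Pa), length >= 4.
#' @param factor fence multiplier (default 1.5).
#' @return list of class \code{outlier_summary}: \code{outlier_idx},
#'   \code{outlier_values}, \code{q1}, \code{q3}, \code{iqr}, \code{factor},
#'   \code{fences} (length 2), \code{z_scores} (leave-one-out, of flagged
#'   values), \code{all_z_ge_3}, \code{retained} (values with outliers
#'   removed).
#' @export
detect_outliers <- function(values, factor = 1.5) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L)
    stop("need at least 4 values for quartile-based outlier detection")
  qs <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2L] - qs[1L]
  fences <- c(qs[1L] - factor * iqr, qs[2L] + factor * iqr)
  out_idx <- which(values < fences[1L] | values > fences[2L])
  z <- vapply(out_idx, function(i) {
    rest <- values[-i]
    s <- stats::sd(rest)
    if (s == 0) Inf else (values[i] - mean(rest)) / s
  }, numeric(1))
  structure(list(outlier_idx = out_idx, outlier_values = values[out_idx],
                 q1 = qs[1L], q3 = qs[2L], iqr = iqr, factor = factor,
                 fences = fences, z_scores = z,
                 all_z_ge_3 = length(z) == 0L || all(abs(z) >= 3),
                 retained = if (length(out_idx)) values[-out_idx] else values),
            class = "outlier_summary")
}

#' Mean and standard error of a group of per-cell moduli
#'
#' @param values numeric vector (after outlier removal), length >= 2.
#' @return list(mean, sem, n) with \code{sem = sd(values) / sqrt(n)}
#'   (sample SD, n - 1 denominator).
#' @export
summarize_modulus <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("need at least 2 values for a standard error")
  list(mean = mean(values), sem = sem(values), n = length(values))
}

#' Two-sample comparison of group moduli
#'
#' Welch's unequal-variance t test by default (group sizes and variances
#' differ between cohorts); the pooled-variance variant is selectable.
#' Two-sided p values throughout. If both groups have zero variance and
#' equal means the test is undefined and p = 1 is reported.
#'
#' @param a,b numeric vectors (per-cell moduli after outlier removal),
#'   each length >= 2.
#' @param kind "welch" or "pooled".
#' @param alpha significance level (default 0.05).
#' @return list of class \code{comparison_result}: \code{t}, \code{df},
#'   \code{p}, \code{alpha}, \code{significant} (p < alpha), \code{kind},
#'   \code{mean_a}, \code{mean_b}.
#' @export
compare_groups <- function(a, b, kind = c("welch", "pooled"), alpha = 0.05) {
  kind <- match.arg(kind)
  stopifnot(length(a) >= 2L, length(b) >= 2L, alpha > 0, alpha < 1)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2, p = 1)
    } else {
      res <- list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = (kind == "pooled"))
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(c(res, list(alpha = alpha, significant = res$p < alpha,
                        kind = kind, mean_a = mean(a), mean_b = mean(b))),
            class = "comparison_result")
}

#' Indentation-order trend
#'
#' For each curve index i >= 2, the mean over cells of the step change
#' \code{E_i - E_(i-1)} and of its magnitude, using each cell's QC-passing
#' fits; pairs with a missing (QC-dropped) member are skipped. The signature
#' of the first-indentation repositioning effect is that the i = 2 step
#' dominates.
#'
#' @param cells list of \code{cell_result} (from \code{\link{run_bundle}});
#'   excluded cells are used too as the trend needs only >= 2 passing curves.
#' @param max_index highest curve index to tabulate (default 15).
#' @return data.frame(index, mean_dE, mean_abs_dE, n_pairs), index 2..max.
#' @export
indentation_trend <- function(cells, max_index = 15L) {
  out <- lapply(2L:max_index, function(i) {
    steps <- vapply(cells, function(cr) {
      e <- cr$E_by_index
      ii <- as.character(i); im <- as.character(i - 1L)
      if (ii %in% names(e) && im %in% names(e)) e[[ii]] - e[[im]] else NA_real_
    }, numeric(1))
    steps <- steps[is.finite(steps)]
    data.frame(index = i,
               mean_dE = if (length(steps)) mean(steps) else NA_real_,
               mean_abs_dE = if (length(steps)) mean(abs(steps)) else NA_real_,
               n_pairs = length(steps))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group-level population summary
#'
#' Applies \code{\link{detect_outliers}} then \code{\link{summarize_modulus}}
#' per group, and runs \code{\link{compare_groups}} on every group pair.
#'
#' @param cell_df data.frame from \code{\link{cell_table}} (included cells
#'   are used).
#' @param factor Tukey fence multiplier.
#' @param kind,alpha passed to \code{\link{compare_groups}}.
#' @return list with \code{groups} (data.frame: group, n_input, n_outliers,
#'   n_retained, mean_Pa, sem_Pa, all_z_ge_3), \code{outliers} (data.frame:
#'   group, cell_id, E_Pa, z), \code{comparisons} (data.frame: group_a,
#'   group_b, t, df, p, significant).
#' @export
population_summary <- function(cell_df, factor = 1.5,
                               kind = "welch", alpha = 0.05) {
  inc <- cell_df[cell_df$included & is.finite(cell_df$E_cell_Pa), , drop = FALSE]
  by_g <- split(inc, inc$group)
  retained <- list()
  grows <- list(); orows <- list()
  for (g in names(by_g)) {
    v <- by_g[[g]]$E_cell_Pa
    os <- detect_outliers(v, factor = factor)
    retained[[g]] <- os$retained
    sm <- summarize_modulus(os$retained)
    grows[[g]] <- data.frame(group = g, n_input = length(v),
                             n_outliers = length(os$outlier_idx),
                             n_retained = sm$n, mean_Pa = sm$mean,
                             sem_Pa = sm$sem, all_z_ge_3 = os$all_z_ge_3,
                             stringsAsFactors = FALSE)
    if (length(os$outlier_idx))
      orows[[g]] <- data.frame(group = g,
                               cell_id = by_g[[g]]$cell_id[os$outlier_idx],
                               E_Pa = os$outlier_values, z = os$z_scores,
                               stringsAsFactors = FALSE)
  }
  gs <- names(by_g)
  crows <- list()
  if (length(gs) >= 2L) {
    for (i in seq_len(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
      cmp <- compare_groups(retained[[gs[i]]], retained[[gs[j]]],
                            kind = kind, alpha = alpha)
      crows[[paste(gs[i], gs[j])]] <-
        data.frame(group_a = gs[i], group_b = gs[j], t = cmp$t, df = cmp$df,
                   p = cmp$p, significant = cmp$significant,
                   stringsAsFactors = FALSE)
    }
  }
  list(groups = do.call(rbind, c(unname(grows), list(make.row.names = FALSE))),
       outliers = if (length(orows))
         do.call(rbind, c(unname(orows), list(make.row.names = FALSE)))
       else NULL,
       comparisons = if (length(crows))
         do.call(rbind, c(unname(crows), list(make.row.names = FALSE)))
       else NULL)
}
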