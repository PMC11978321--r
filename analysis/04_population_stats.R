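#!/usr/bin/env Rscript
# 04: population statistics.
#
# Tukey-fence outlier removal (1.5 x IQR, leave-one-out z validation),
# group mean +/- SEM, pairwise Welch comparisons at alpha 0.05, and the
# indentation-order trend that motivates dropping the first indentation.

suppressMessages(library(afmcell))

res <- readRDS("scratch/run_bundle_cache.rds")
cells <- cell_table(res$cells)
truth <- read.csv("results/cohort_truth.csv")

pop <- population_summary(cells, factor = 1.5, kind = "welch", alpha = 0.05)
write.csv(pop$groups, "results/group_summary.csv", row.names = FALSE)
write.csv(pop$comparisons, "results/comparisons.csv", row.names = FALSE)
if (!is.null(pop$outliers))
  write.csv(pop$outliers, "results/outliers.csv", row.names = FALSE)

message("group summaries (mean +/- SEM after outlier removal):")
for (i in seq_len(nrow(pop$groups)))
  message(sprintf("  %-6s n=%2d -> %2d retained: %6.1f +/- %4.1f Pa",
                  pop$groups$group[i], pop$groups$n_input[i],
                  pop$groups$n_retained[i], pop$groups$mean_Pa[i],
                  pop$groups$sem_Pa[i]))

if (!is.null(pop$outliers)) {
  hit <- merge(pop$outliers, truth, by = "cell_id")
  message(sprintf("outliers flagged: %d (of which %d planted); all |z| >= 3: %s",
                  nrow(pop$outliers), sum(hit$outlier),
                  all(pop$groups$all_z_ge_3)))
}

message("pairwise Welch tests:")
for (i in seq_len(nrow(pop$comparisons)))
  message(sprintf("  %s vs %s: t = %6.2f, p = %8.3g %s",
                  pop$comparisons$group_a[i], pop$comparisons$group_b[i],
                  pop$comparisons$t[i], pop$comparisons$p[i],
                  ifelse(pop$comparisons$significant[i], "*", "")))

tr <- indentation_trend(res$cells)
write.csv(tr, "results/indentation_trend.csv", row.names = FALSE)
message(sprintf("indentation trend: |dE| at step 2 = %.1f Pa vs %.1f Pa mean over steps 3-15",
                tr$mean_abs_dE[1], mean(tr$mean_abs_dE[-1], na.rm = TRUE)))
message("stats -> results/group_summary.csv, comparisons.csv, outliers.csv, indentation_trend.csv")
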