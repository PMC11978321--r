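#!/usr/bin/env Rscript
# 03: apply the per-cell protocol.
#
# Drop QC failures, enforce the 11-survivor inclusion rule, remove the
# first indentation, require >= 10 remaining curves, and average to one
# Young's modulus per cell. Writes the per-cell table and narrates every
# exclusion.

suppressMessages(library(afmcell))

res <- readRDS("scratch/run_bundle_cache.rds")
cells <- cell_table(res$cells)
write.csv(cells, "results/cells.csv", row.names = FALSE)

message(sprintf("%d cells assessed: %d included, %d excluded",
                nrow(cells), sum(cells$included), sum(!cells$included)))
for (r in which(!cells$included))
  message(sprintf("  excluded %s: %s", cells$cell_id[r], cells$reason[r]))
message(sprintf("averaged curves per included cell: %d-%d (median %d)",
                min(cells$n_avg[cells$included]),
                max(cells$n_avg[cells$included]),
                median(cells$n_avg[cells$included])))

truth <- read.csv("results/cohort_truth.csv")
m <- merge(cells[cells$included, ], truth, by = "cell_id")
err <- m$E_cell_Pa / m$E_true_Pa - 1
message(sprintf("recovery vs ground truth: median %+.1f%%, IQR %.1f%%",
                100 * median(err), 100 * IQR(err)))
message("per-cell table -> results/cells.csv")
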