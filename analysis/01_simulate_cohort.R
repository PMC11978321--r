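#!/usr/bin/env Rscript
# 01: simulate the THP-1-style measurement cohort.
#
# Four groups mirroring the wild-type / retronectin / ITGB1-knock-out design
# (group medians 113, 171, 91 and 74 Pa), 20 cells per group (scaled down
# from the study's 39-51 cells per group to keep this driver fast), 15
# indentations per cell at a 1 nN set point, with occasional outlier-stiff
# cells and per-curve acquisition artifacts. Writes the curve bundle in the
# TSV dialect plus the ground-truth table under results/.
#
# Note the measurability floor: with 3.5 um of piezo travel, cells whose
# softest curve cannot reach 1 nN are not acquirable. For the softest group
# (median 74 Pa) this truncates the soft tail, so its recovered mean will
# sit above the nominal median -- the instrument's range, not a pipeline
# bias. 02-04 quantify exactly that.

suppressMessages(library(afmcell))

seed <- 20260918L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cp <- cohort_params(
  groups = list(
    list(label = "WT",    median_E = 113, log_sd = 0.3, n_cells = 20),
    list(label = "WT_RN", median_E = 171, log_sd = 0.3, n_cells = 20),
    list(label = "KO",    median_E = 91,  log_sd = 0.3, n_cells = 20),
    list(label = "KO_RN", median_E = 74,  log_sd = 0.3, n_cells = 20)),
  curves_per_cell = 15,
  first_shift_factor = 0.7,
  outlier_fraction = 0.05, outlier_multiplier = 5,
  artifact_rates = c(short_baseline = 0.02, pinch = 0.02),
  curve_params = synth_curve_params(E_true = 113, contact_frac = 0.22),
  seed = seed)

floor_Pa <- feasible_E_floor(cp$curve_params)
message(sprintf("measurability floor: %.1f Pa (%.1f Pa for the 0.7-shifted first curve)",
                floor_Pa, floor_Pa / 0.7))

bundle <- simulate_cohort(cp)
write_bundle_tsv(bundle, file.path(out_dir, "cohort_bundle"), overwrite = TRUE)
write.csv(bundle$truth, file.path(out_dir, "cohort_truth.csv"),
          row.names = FALSE)

message(sprintf("simulated %d curves over %d cells in 4 groups",
                length(bundle$curves), nrow(bundle$cells)))
message(sprintf("planted outlier cells: %d; curves with artifacts: %s",
                sum(bundle$truth$outlier),
                sum(bundle$truth$artifacts != "none")))
message("bundle -> results/cohort_bundle/, truth -> results/cohort_truth.csv")
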