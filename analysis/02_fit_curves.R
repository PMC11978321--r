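#!/usr/bin/env Rscript
# 02: correct and fit every force curve of the simulated cohort.
#
# Baseline subtraction, contact-point seeding, cantilever-bending
# correction, then the joint (E, contact point) least-squares fit of the
# Sneddon sphere model, with per-curve QC (short baseline, membrane pinch,
# residuals). Writes the per-curve fit table.

suppressMessages(library(afmcell))

bundle <- read_bundle_tsv("results/cohort_bundle")
cfg <- run_config()            # Sneddon sphere, protocol defaults
model <- contact_model(cfg$model, R = bundle$curves[[1]]$R, nu = cfg$nu)

t0 <- Sys.time()
res <- run_bundle(bundle, model = model, config = cfg)
message(sprintf("fitted %d curves in %.1f s", length(res$fits),
                as.numeric(Sys.time() - t0, units = "secs")))

fits <- fit_table(res$fits)
write.csv(fits, "results/curve_fits.csv", row.names = FALSE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(res, "scratch/run_bundle_cache.rds")   # intermediate, not a deliverable

n_flagged <- sum(fits$qc_flags != "")
message(sprintf("QC: %d of %d curves flagged (%s)", n_flagged, nrow(fits),
                paste(names(table(fits$qc_flags[fits$qc_flags != ""])),
                      collapse = ", ")))
message(sprintf("median fitted E %.0f Pa, median max indentation %.2f um",
                median(fits$E_Pa, na.rm = TRUE),
                median(fits$max_indentation_m, na.rm = TRUE) * 1e6))
message("per-curve fits -> results/curve_fits.csv")
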