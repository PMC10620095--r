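#!/usr/bin/env Rscript
# Step 3 — voxel-level connectivity-to-activity model.
#
# Tessellates the cerebellar cortex into 100-um voxels, quantifies
# normalized input and output connectivity strength per voxel, attaches
# the per-voxel fraction of delay-selective units and their mean
# amplitude (from step 2's unit table), and asks which predictor —
# input, output, or their product — best explains preparatory activity
# under 5-fold cross-validation.

library(loopmap)

dir.create("results", showWarnings = FALSE)
if (!file.exists("results/unit_selectivity.csv"))
  stop("run analysis/02_selectivity_map.R first")

cfg_an <- gen_config(seed = 20260926)
an <- gen_anatomy(cfg_an, n_mice = 7)
outputs <- gen_anatomy(gen_config(seed = 20260927), n_mice = 5)$outputs

# unit positions regenerated from the step-2 configurations
regen <- function(zones, amp, frac, seed, n) {
  cfg <- gen_config(seed = seed, select_amp_hz = amp, frac_selective = frac,
                    trials_per_type = 40)
  gen_ephys(cfg, n_units = n, region_labels = zones)$units
}
cl <- classify_regions(
  normalized_density(an$inputs, cfg_an$atlas, hemisphere = "combine"),
  normalized_density(outputs, cfg_an$atlas, hemisphere = "R"))
zones_by_region <- split(cl$zone, cl$region)
units <- c(regen(zones_by_region$conjunction, 8, 0.45, 101, 120),
           regen(zones_by_region$`input-dominant`, 4, 0.10, 102, 90),
           regen(zones_by_region$`output-dominant`, 4, 0.10, 103, 130))
sel <- read.csv("results/unit_selectivity.csv")
stopifnot(nrow(sel) == length(units))

unit_tab <- data.frame(
  x_um = sapply(units, `[[`, "x_um"),
  y_um = sapply(units, `[[`, "y_um"),
  z_um = sapply(units, `[[`, "z_um"),
  delay_selective = sel$delay_sig,
  amplitude_hz = sel$delay_amp_hz)

# coarser voxels than the 100-um display grid keep >= several units/voxel
grid <- voxelize(an$inputs, outputs, units = unit_tab, edge_um = 400)
model <- connectivity_activity_model(grid, folds = 5, seed = 1)
write.csv(model, "results/voxel_model_comparison.csv", row.names = FALSE)

cat("Voxels:", nrow(grid), "| with recorded units:",
    sum(grid$n_units > 0), "\n")
print(model)
win <- model$predictor[model$winner & model$activity == "frac_selective"]
cat("Best predictor of the fraction of delay-selective units:", win, "\n")
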