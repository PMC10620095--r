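#!/usr/bin/env Rscript
# Step 5 — movement control: does video-explained activity account for
# trial-type selectivity?
#
# Fits the lagged L1-penalized Poisson GLM of spiking on 32-dimensional
# video embeddings for two simulated unit populations — one whose
# selectivity is carried entirely by trial-type-dependent movements, one
# whose selectivity is intrinsic — and compares delay-epoch selectivity
# before and after subtracting the movement prediction.

library(loopmap)

dir.create("results", showWarnings = FALSE)

run_units <- function(n, seed0, type_offset = 0, intrinsic = 0) {
  rows <- lapply(seq_len(n), function(i) {
    cfg <- gen_config(seed = seed0 + i)
    es <- gen_embeddings(cfg, n_trials = 70, n_units = 1, coupled_frac = 1,
                         type_offset = type_offset,
                         intrinsic_amp_hz = intrinsic)
    u <- es$units[[1]]
    fit <- fit_lagged_glm(es, u$counts, lags = -2:2, relax = TRUE)
    rs <- residual_selectivity(es, u$counts, fit)
    data.frame(unit = i, lag = fit$lag, test_r2 = fit$test_r2,
               orig_amp_hz = rs$original$amplitude,
               resid_amp_hz = rs$residual$amplitude,
               resid_sig = isTRUE(rs$residual$significant))
  })
  do.call(rbind, rows)
}

movement <- run_units(40, 88000, type_offset = 0.5)
intrinsic <- run_units(40, 89000, intrinsic = 8)
movement$population <- "movement-borne"
intrinsic$population <- "intrinsic"
out <- rbind(movement, intrinsic)
write.csv(out, "results/movement_glm_control.csv", row.names = FALSE)

cat("Movement-borne selectivity population (n = 40):\n")
cat("  median test R^2:", round(median(movement$test_r2), 3), "\n")
cat("  selectivity", round(mean(movement$orig_amp_hz), 1), "Hz ->",
    round(mean(movement$resid_amp_hz), 2), "Hz after subtraction;",
    sum(movement$resid_sig), "unit(s) remain significant\n")
cat("Intrinsic selectivity population (n = 40):\n")
cat("  selectivity", round(mean(intrinsic$orig_amp_hz), 1), "Hz ->",
    round(mean(intrinsic$resid_amp_hz), 1), "Hz after subtraction;",
    sum(intrinsic$resid_sig), "units remain significant\n")
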