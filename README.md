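# loopmap

Analysis pipeline linking a mesoscale cortico-cerebellar connectome to an
electrophysiological activity map of the cerebellar cortex during a
delayed-response licking task.

Frontal cortex (ALM) and the cerebellum jointly maintain *preparatory
activity* — delay-epoch firing that predicts upcoming lick direction.
`loopmap` implements the full computational chain for asking where in the
cerebellar cortex that activity lives relative to the anatomical loop:

- **Connectivity mapping.** Per-mouse normalized densities of annotated
  mossy-fiber terminals (ALM input) and Purkinje-cell somas (ALM-projecting
  output): `d_l = f_l / V_l`, where `f_l` is the fraction of a mouse's
  points in lobule `l` and `V_l` the lobule volume in 10-µm reference
  voxels. Lobules split into medial/lateral sub-lobules at fixed
  mediolateral thresholds; zones classified by a conjunctive threshold
  (θ = 10⁻¹¹) into conjunction / input-dominant / output-dominant /
  excluded. 3-D Gaussian KDE maps, 100-µm voxel tessellation, and a
  cross-validated comparison of input, output, and input × output as
  predictors of preparatory activity.
- **Selectivity statistics.** Epoch spike-count selectivity (two-tailed
  t-test, P < 0.01) with a split-trial estimator: the preferred trial type
  is fixed on 15 held-out trials per type and the amplitude
  `S = r_pref − r_nonpref` is computed on the remaining trials, making the
  estimator unbiased under the null. Ramping classification and
  population selectivity traces.
- **Purkinje-cell typing.** CS-triggered simple-spike pause validation,
  z-scored 102-bin PSTHs, and response-type clustering by top-6 PC scores
  with silhouette-selected k-means (k = 1–20, Euclidean distance).
- **Perturbation statistics.** Photostimulation Δperformance with a
  three-level hierarchical bootstrap (mice → sessions → trials; one-sided
  sign-flip p-value, α = 0.025) and Benjamini–Hochberg step-up correction
  over the 16 stimulation spots.
- **Movement control.** Lagged (±5 frame steps) L1-penalized Poisson GLM
  predicting spike counts from 32-dimensional video embeddings
  (`R² = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)²`), and trial-type selectivity recomputed
  on the prediction residuals.

A seeded synthetic-data generator (`gen_config`, `gen_anatomy`,
`gen_ephys`, `gen_behavior`, `gen_embeddings`, `gen_typed_psths`) emulates
the data structure of such a study, so the whole chain runs end to end
without raw recordings. The numbered scripts in `analysis/` are the
workflow's drivers and write their tables under `results/`; the methods
vignette (`vignettes/loopmap-methods.Rmd`) documents every modeling
choice.

## Worked example

```r
library(loopmap)

cfg <- gen_config(seed = 11)
an  <- gen_anatomy(cfg, n_mice = 4)
cl  <- classify_regions(
  normalized_density(an$inputs,  cfg$atlas, hemisphere = "combine"),
  normalized_density(an$outputs, cfg$atlas, hemisphere = "R"),
  theta = 1e-11)
table(cl$region)
#>     conjunction  input-dominant output-dominant        excluded
#>               4               4               8               3
cl$zone[cl$region == "conjunction"]
#> [1] "Lob VII"    "med-SIM"    "med-Crus 1" "med-Crus 2"
```

The four conjunction zones — medial simplex, medial Crus 1/2, and vermal
lobule VII — are the regions carrying both ALM input and ALM-projecting
output; the pipeline's downstream stages test whether preparatory activity
and behavioral impact concentrate there. Running the activity map on the
same conditions (`analysis/02_selectivity_map.R`) prints, for 340
synthetic units:

```
Fraction delay-selective by region:
    conjunction  input-dominant output-dominant
          0.475           0.111           0.123
```

and the response-typing stage recovers the number of complex-spike
response motifs from synthetic PSTHs:

```r
sim <- gen_typed_psths(n_per_type = 40, noise_sd_frac = 0.3, seed = 1)
cluster_response_types(sim$Z)$k
#> [1] 6
```

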