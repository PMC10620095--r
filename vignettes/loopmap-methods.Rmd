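---
title: "Methods: mapping a cortico-cerebellar loop for motor planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a cortico-cerebellar loop for motor planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmap)
```

## The problem

During a delayed-response licking task, frontal cortex (ALM) and the
cerebellum maintain preparatory activity — delay-epoch firing that predicts
the upcoming lick direction. `loopmap` implements the analysis chain that
relates a mesoscale map of ALM–cerebellar connectivity to an
electrophysiological activity map: where do ALM inputs (mossy-fiber
terminals) and ALM-projecting outputs (Purkinje cells) land in the
cerebellar cortex, and is preparatory activity enriched where both
overlap? The package provides every computational stage — density mapping
and region classification, spike-train selectivity statistics,
complex-spike response typing, hierarchical-bootstrap perturbation
statistics, and a movement-GLM control — together with a seeded synthetic
generator that emulates the data structure of such a study, so the whole
chain runs and is tested end to end without any raw recordings. The
numbered scripts under `analysis/` are the workflow's narrative drivers;
the package functions are the interface for programmatic use.

## Reference geometry

The atlas (`cb_atlas()`) is parametric: each lobule is an axis-aligned box
with a realistic CCF-scale volume, expressed as a count of 10-µm reference
voxels (1 mm³ = 10⁶ voxels). This is deliberately not the Allen mesh — no
download, no mesh arithmetic — but it preserves everything the density
pipeline depends on: per-lobule volumes, mediolateral extents, and the
med/lat split thresholds (fastigial pathway: SIM 2.5 mm, Crus 1 3.2 mm,
Crus 2 2.7 mm from the midline; dentate pathway: SIM 2.2, Crus 1 2.2,
Crus 2 1.7, PRM 2.2 mm). Points exactly at a threshold are lateral; the
boxes of the split sub-lobules adjoin at the threshold so label and
geometry cannot disagree. A config flag (`collapse_posterior`) emulates
the missing posterior tip of the reference template by collapsing
posterior points onto a boundary plane; it is off by default.

Trial time is shared across all electrophysiology: go cue at t = 0, delay
epoch [−1.3, 0) s, sample epoch [−2.6, −1.3) s, a 0.5-s pre-sample
baseline window, and a response window of [0, 1.5) s. The response-epoch
analysis window is not stated by the source methods; we fix it at the
1.5-s answer window and treat that as a package convention.

## Normalized connectivity density and region classes

For each mouse, the fraction of annotated points per lobule (or
sub-lobule) is the count divided by the mouse's total — this normalizes
away infection-rate variability — and the normalized density divides the
fraction by the lobule volume in 10-µm voxels. Summaries (mean ± s.e.m.)
are across mice, never pooled points. Input maps combine hemispheres;
output maps use a single hemisphere (half volumes); both conventions are
caller-overridable. Classification thresholds the *cross-mouse mean*
densities at θ = 10⁻¹¹ (the volume unit makes θ interpretable on the
fraction-per-voxel scale): above both thresholds → conjunction, input
only → input-dominant, output only → output-dominant, neither → excluded.
Applying θ per mouse instead is possible via the per-mouse profile table,
but the mean convention matches how such maps are plotted and is the
package default.

The synthetic generator's default intensities place points only in zones
with a projection; zones below threshold get intensity zero. At
desk-scale totals (10⁴–10⁵ points) even one stray annotation would clear
θ, so sparse background mis-annotation is intentionally not modeled —
passing classification tests therefore demonstrate the arithmetic and the
threshold logic, not robustness to annotation noise.

The kernel-density map is a 3-D Gaussian-product KDE (σ = 20 µm per axis,
the stated kernel width; the kernel family itself is our choice), computed
per mouse and averaged. No installed package provides a 3-D weighted KDE
at arbitrary evaluation points, so the kernel sum is written directly and
checked against a brute-force double loop in the tests.

Voxel analysis bins points at `floor(coordinate/edge)` with a 100-µm
default edge; voxels tile space evenly and may span lobule boundaries.
The connectivity→activity comparison fits three single-predictor linear
models (input, output, input × output) for each activity measure and
reports 5-fold cross-validated R² over voxels with recorded units, with a
fixed fold seed. The source methods do not state a validation protocol
for this comparison; cross-validation is the package's choice, and a
zero-variance predictor is reported as undefined rather than fitted.

## Trial-type selectivity

A unit is *selective* in an epoch when its epoch spike counts
differentiate correct 'lick left' from 'lick right' trials (two-tailed
Welch t-test, P < 0.01 — the unequal-variance variant is our choice; the
source states only "two-tailed t-test"). The significance test uses all
correct trials, including the preference subset (the alternative —
excluding it — is a documented switch-point but not implemented as an
option). The *amplitude* uses the split-trial estimator: the preferred
type is fixed on a held-out subset (the first 15 chronological trials of
each type; a seeded random subset is available) and the selectivity is
the preferred-minus-non-preferred rate difference on the remaining trials
only. Without the split, taking the absolute difference on the same
trials is positively biased under the null; a regression test
demonstrates both facts. For photostimulation analyses the estimator
pools correct and error trials grouped by instructed type
(`correct_only = FALSE`), since perturbation can flip the upcoming
choice.

Ramping classification uses per-trial delay-minus-baseline rate
differences per type. The stated test ("Mann–Whitney U against 0") is a
one-sample problem; we implement it as the Wilcoxon signed-rank test on
the per-trial differences, which is the standard one-sample counterpart.
Direction (up/down) comes from the last 500 ms of the delay versus
baseline, for the type with the largest rate change; units without a
significant delay change are excluded.

## Purkinje-cell typing

Purkinje identity is validated by the complex-spike-triggered
simple-spike pause: a ±50-ms cross-correlogram in 1-ms bins, baseline
from the negative lags, pause statistic = post-CS (0–10 ms] rate /
baseline, accept below 0.5. Fewer than 20 CS events is indeterminate,
mirroring the practice of discarding ambiguous CS clusters.

Response typing z-scores each unit's pooled-type PSTH (200-ms bins)
against the pre-sample baseline (mean and sd of per-trial baseline-bin
rates; sd floor 10⁻⁶ Hz with logged exclusion) and linearly interpolates
the trace onto 102 evenly spaced bins — the downsampling method is not
stated at the source; interpolation is ours. The 102 bins span the
package trial window (−3.1 to +1.5 s); the exact span is ambiguous at the
source and flagged as a convention. Clustering takes the top-6
principal-component scores, runs seeded k-means (50 restarts) for each
candidate k in 1–20, and selects the k with the largest mean Euclidean
silhouette. Silhouette is undefined at k = 1, so k = 1 ("no structure")
is reported only when every k ≥ 2 silhouette falls below 0.25. We
initially used 0.1 for that bound, but pure isotropic noise at these
problem sizes (tens to hundreds of units, 6 score dimensions) yields
silhouettes of ~0.2, so 0.1 can never fire; 0.25 sits above the measured
noise floor and well below the ≥ 0.38 observed for genuinely structured
data. The archetype templates (`cs_response_templates()`) encode the six
qualitative CS response motifs — epoch-transition transients, a
trial-start transient (plausibly sound-driven in real data; no mechanism
is modeled), pre-response buildup, response elevation, response
suppression, and sample-epoch modulation.

## Perturbation statistics

Performance is the fraction of correct choices among scoreable trials
(early-lick and ignore trials excluded from the denominator), computed
per condition and per instructed type. Δperformance is
stimulation-minus-control, pooled over sessions and mice.

The hierarchical bootstrap resamples, with replacement and at observed
sizes, (1) mice, (2) sessions within each resampled mouse, (3) trials
within each resampled session — stimulation and control trials within
their own stratum so both arms stay represented (the source does not
state its trial strata; this is our choice). The one-sided p-value is the
fraction of replicates whose Δ has the sign opposite the observed Δ, with
zero-Δ replicates counting one half; p = 0 is reported as 1/n_reps. The
default is 10,000 replicates (the study scale of 10⁶ is available by
argument but is desk-impractical). Because the statistic is a fraction of
binary outcomes, trial-level resampling within a session is
distributionally identical to drawing Binomial(n, k/n) counts; the
default fast path does exactly that, and a literal index-resampling path
(`method = "index"`) backs the structural tests.

A property worth knowing: under a *homogeneous* null (no stimulation
effect, no session or mouse heterogeneity in the stim-control gap) this
test is conservative. The observed Δ compares two arms that share the
same mice and sessions, so higher-level effects cancel in Δ, yet the
three resampling levels each re-inject trial-level noise into the
bootstrap distribution — its sd is roughly √3 times the sampling sd of Δ,
and the nominal α = 0.025 test rejects far less than 2.5% of null
datasets. The acceptance suite measures this honestly (and fails the
nominal-calibration expectation); power for realistic effect sizes (a
20-point drop at 10 mice × 4 sessions × 200 trials) is essentially 1.
Multiple comparisons over the 16 grid locations use the
Benjamini–Hochberg step-up rule (via `p.adjust`, tested against a
brute-force evaluation of the sorted-rank definition).

## Movement GLM

The movement control predicts a unit's spike counts (binned at the 25-ms
or 17-ms camera frame step; the per-session step is a field, never
resampled) from the 32-dimensional video embeddings with an L1-penalized
Poisson GLM. The source describes a "logistic link function with Poisson
spiking statistics", which is internally inconsistent; we use the
canonical log link. A separate model is fitted at each lag from −5 to +5
frame steps; parameters are fitted on 80% of trials (the split is fixed
once and shared by all lags), the penalty strength is chosen on a
validation split of the training trials by held-out R², and the lag with
the largest test R² is retained. R² is the stated closed form
1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)².

For the residual control the observed rate is smoothed with a centered
boxcar (425 ms at 25-ms steps, 340 ms at 17-ms steps), the prediction is
smoothed with the *same* window — otherwise epoch-onset transients enter
only one series and masquerade as residual selectivity — and epoch
selectivity is recomputed on the residuals with the same held-out
preference scheme. Plain L1 weights are shrunk toward zero, which leaves
a systematic ~5% of any movement-borne rate modulation in the residual;
`fit_lagged_glm(..., relax = TRUE)` therefore refits the L1-selected
support by an unpenalized Poisson GLM on the training trials (relaxed
lasso) before subtraction. With both measures the control behaves as it
should: when the generator routes all selectivity through trial-type
dependent embeddings, residual significance collapses to the test's
nominal level; when selectivity is intrinsic, the residual amplitude
stays within ~±20% of the original.

## The synthetic generator

All randomness flows from one root seed through a labelled
stream-splitting scheme (`split_seed`), so anatomy, spikes, behavior and
embeddings can be regenerated independently. What it emulates: per-zone
Poisson point counts scaled by log-normal per-mouse infection rates;
inhomogeneous-Poisson spike trains with delay-epoch ramps (a linear ramp
normalized so the configured amplitude is the *mean* delay-epoch
increment; a step profile is available) and enforced post-CS pauses;
Bernoulli trial outcomes with per-(spot, epoch) photostimulation biases
over a 4 × 4 grid × 3 epochs; and AR(1) latent embeddings (coefficient
0.8, i.e. ~110-ms decorrelation at 25-ms frames — the timescale of
orofacial movement video, and short enough that adjacent-frame lags are
identifiable) driving log-linear unit rates at a configurable lag. Error
trials are independent Bernoulli flips with no within-session
autocorrelation; early-lick and ignore trials occur at configured rates.

What it does not emulate — and hence what green tests do *not*
demonstrate about real data: annotation background noise, electrode
drift and sorting errors, between-session non-stationarity, correlated
trial outcomes, realistic video statistics, or any anatomical shape
beyond boxes.

## Problem sizes and numerical choices

The test suite runs the stages at the sizes the analyses are specified
at where that is affordable on a desk machine: 2,000 null units for
estimator calibration, 500 null datasets × 2,000 bootstrap replicates
for the type-I measurement, 1,000 fuzzed p-vectors for the BH oracle,
100 seeds for the voxel-model comparison, 100 units for lag recovery and
for each residual-control population, and 240 synthetic PSTHs (40 per
archetype, noise sd = 0.3 of peak amplitude) for cluster-number
recovery. Baseline sd floors, the k-means restart count (50), tie rules
(lateral at the split threshold; zero-Δ replicates count one half) and
fold seeds are all fixed and documented above.

## Known limitations

The atlas is a box model: distances to real lobule boundaries are not
meaningful, only labels, volumes and mediolateral positions are. The
hierarchical bootstrap is conservative under homogeneous nulls (above).
The silhouette noise floor (0.25) was calibrated at these problem sizes
and should be re-examined for much larger unit counts or different score
dimensionality. The chi-squared comparison of response-type proportions
across regions is descriptive of real data and is not reproduced here.
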