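# conshab — multiscale consensus presence-only habitat modeling

`conshab` is an R implementation of the habitat-modeling workflow used in
landscape-scale carnivore conservation planning, exercised end to end on
synthetic landscapes with a known virtual species. It is aimed at spatial
ecologists who want a fully scriptable, testable version of the familiar
GIS-plus-Maxent pipeline: telemetry screening, raster covariate
engineering, presence-background suitability modeling with two model
families, cross-validated accuracy assessment, consensus mapping at two
spatial scales, and threat/protection accounting.

## The models

Two complementary presence-only suitability models are fitted per extent:

* **Maximum entropy** — a Gibbs distribution over background locations,
  `p(x) = exp(Σ λ_j f_j(x)) / Z`, with linear, quadratic, and hinge
  features per covariate and an L1 penalty `Σ β_j |λ_j|` whose per-feature
  weights follow the published Maxent defaults (class-level regularization
  interpolated on presence count, scaled by the feature's presence standard
  error). Fitting is by accelerated proximal gradient with backtracking;
  map output uses the cloglog transform `1 − exp(−e^H · raw)`.
* **Mahalanobis distance** — suitability is the chi-square upper-tail
  probability of `D² = (x−μ)ᵀ Σ⁻¹ (x−μ)`, where `μ, Σ` are the mean and
  covariance of the covariates at the presence locations; 1 at the
  presence centroid.

Accuracy per cross-validation fold uses AUC, the continuous Boyce index,
and — after binarizing at the maximum sensitivity-plus-specificity
threshold — sensitivity, specificity, and TSS (= sens + spec − 1).
Iteration surfaces are averaged into a consensus, thresholded with the mean
Maxent max-SSS value, local management-unit models are mosaicked statewide,
and the local/state binaries combine into habitat categories
(1·local + 2·state) whose areas feed overlay accounting against
inundation, development, and protection masks.

Because no public telemetry or geodata accompany the workflow, the package
ships a seeded generator (`sim_config()`, `make_landscape()`,
`simulate_telemetry()`, `gen_threat_masks()`) producing autocorrelated
covariates, a logistic virtual species, habitat-biased mixed VHF/GPS
telemetry with DOP noise and capture/mortality records, and
elevation-driven threat masks — so parameter recovery and end-to-end
accuracy are verifiable against ground truth.

## Worked example

```r
library(conshab)
run <- run_pipeline(run_config(seed = 1))
print(run)
```

```
<pipeline_run>
  fixes: 32800 raw -> 8341 used
  state:  consensus AUC 0.865, Boyce 0.992, TSS 0.603, threshold 0.294, habitat 94.8 km2
  local:  consensus AUC 0.921, Boyce 0.992, TSS 0.722, threshold 0.217, habitat 112.4 km2
```

Reading this: of 32,800 simulated fixes, 8,341 survive screening (capture
and mortality records, GPS fix status, DOP > 7, underage animals, the
30-locations-in-12-months and 3-distinct-months rules) and 5-h subsampling.
Held-out consensus accuracy is reported leave-fold-out: the local-scale
consensus discriminates presences from background with AUC 0.92 and is
almost perfectly calibrated (Boyce 0.99). The thresholds are the averaged
max-SSS values from the Maxent iterations; applying them yields 94.8 km²
of state-scale and 112.4 km² of local-scale habitat on the 576 km²
synthetic landscape, which `run$category$areas` breaks into
local-only/state-only/both categories and `run$overlay` intersects with
the threat masks.

The numbered drivers under `analysis/` run the same study stage by stage
(simulate → screen → covariates → fit/evaluate/consensus → worked
examples), writing tables and ASCII-grid rasters under `results/`.

The package also ships the published statewide black bear accounting
tables (`bear_reference_tables()`) as plain-text worked examples: the
area-summation and percentage operations reproduce their internally
consistent printed figures exactly (e.g. per-unit local areas sum to
23,749.63 km²; 226.67 km² flooded of 23,749.63 km² local habitat is
0.95%).

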