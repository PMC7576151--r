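---
title: "Multiscale consensus habitat modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale consensus habitat modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`conshab` implements a complete presence-only habitat modeling workflow of
the kind used for statewide carnivore conservation planning: screen
telemetry, engineer raster habitat covariates, fit two complementary
suitability models under cross-validation at two spatial scales, assess
accuracy, average the iterations into a consensus surface, binarize it at
the maximum sensitivity-plus-specificity threshold, mosaic local
management-unit models into one statewide map, and account for overlap with
threat and protection layers. Because the workflow is exercised on synthetic
landscapes with a known virtual species, every stage is testable end to end
and the model-recovery claims can be checked against ground truth.

## The models

**Maximum entropy (Maxent).** The presence-background model is a Gibbs
distribution over background locations,

$$p_\lambda(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z(\lambda)},$$

where the features $f_j$ are, per covariate, a linear term, a quadratic
term, and forward/reverse hinge features with knots at training quantiles
(15 per direction by default). Covariates are min-max normalized to $[0,1]$
on their training range, and evaluation on new data clamps to that range.
Fitting maximizes the mean presence log-probability minus an L1 penalty
$\sum_j \beta_j |\lambda_j|$, with the per-feature penalty following the
published Maxent defaults: a feature-class regularization parameter
interpolated on the presence count, times the feature's presence standard
error. The default map output is the cloglog transform
$1 - \exp(-e^H \cdot \text{raw})$, with $H$ the entropy of the fitted
distribution over the background; raw and cloglog outputs are
rank-equivalent, so threshold-independent accuracy is unaffected by this
choice. Product and threshold features are omitted: hinge features subsume
threshold features, and the workflow's accuracy checks do not require
interactions. Which output fed the original thresholding workflow is not
documented; cloglog is assumed, matching the default of the Maxent version
this emulates.

The optimizer is accelerated proximal gradient (FISTA) with backtracking
line search, soft-threshold proximal steps, and a restart rule that keeps
the penalized objective monotone. Iteration stops when the relative change
in the objective drops below $10^{-6}$; exceeding the iteration cap is an
error with diagnostics, never a silent partial fit. The fit is
deterministic given its inputs.

**Mahalanobis distance.** The second family is a true presence-only model:
habitat is characterized by the mean $\mu$ and covariance $\Sigma$ of the
covariates at the presence locations, and each cell's suitability is the
chi-square upper-tail probability of
$D^2 = (x-\mu)^\top \Sigma^{-1} (x-\mu)$ with degrees of freedom equal to
the number of variables ("probability" output): 1 at the presence centroid
and strictly decreasing in $D^2$. $\Sigma^{-1}$ is applied through a
Cholesky factorization; positive-definiteness is checked against a
$10^{-10}$ relative floor on the smallest eigenvalue, and violations raise
an error naming the most collinear column pair.

**Variable selection.** Maxent uses a reverse step-wise rule: fit all
variables, drop those at or below 1% permutation contribution, and among
flagged correlated pairs ($|r| \ge 0.7$ by default; the screen threshold is
configurable because the original workflow reports excluded pairs but no
cutoff) keep the higher-contribution member; iterate to stability (at most
5 rounds). Percent contribution is permutation importance — the drop in
training gain when a variable's values are shuffled across presence and
background rows, averaged over 10 permutations and normalized to 100 —
rather than path-dependent per-iteration gain bookkeeping, which is
solver-specific. Mahalanobis selection is PCA-guided: contributions are
summed squared loadings (weighted by variance share) over the components
covering 80% of variance, and the lowest-contribution variable is dropped
iteratively. The stopping rule — all remaining relative contributions above
5%, or two variables left — is this package's explicit stand-in for a
mechanism the source workflow describes but does not quantify.

## Evaluation and thresholding

Five measures are computed per model iteration: rank-based AUC (ties count
one half) against the iteration's background sample, which stands in for
the negative class since true absences do not exist in presence-only data;
the continuous Boyce index — Spearman correlation of predicted-to-expected
presence ratios against window midpoint over 101 overlapping suitability
windows of width one tenth of the suitability range (the conventional
"default moving window", made explicit and configurable here); and, after
binarization at the maximum sensitivity-plus-specificity threshold,
sensitivity, specificity, and TSS = sensitivity + specificity − 1. The
threshold rule is `score >= t` (the cutoff itself is habitat) so binary
maps are bit-reproducible, and the candidate set is every distinct observed
score with ties broken toward the smallest maximizer. Per-extent consensus
thresholds average the per-iteration Maxent max-SSS values *unrounded*;
whether the original workflow averaged before or after rounding is
unstated.

Held-out consensus accuracy is reported leave-fold-out: for each fold the
ensemble of all iteration surfaces except the two trained with that fold's
presences is scored on the fold's held-out points.

## Consensus, mosaicking, and overlay accounting

Consensus surfaces are cellwise means of all iteration surfaces for an
extent (both families enter unrescaled — both live in $[0,1]$; an optional
min-max rescale flag exists and is off by default). The binarization
threshold comes from the Maxent iterations only. Local models are fitted on
management units buffered by 20 km, but buffers are fitting context only:
at mosaic time every cell takes its value from the unit that contains it,
which resolves an overlap ambiguity the source workflow leaves open.
Combining scales encodes categories as $1\cdot\text{local} +
2\cdot\text{state}$ — a weighted sum, because a plain sum cannot
distinguish local-only from state-only habitat. All areas are cell counts
times $(\text{cellsize}/1000)^2$, so category tables reconcile exactly with
their binary inputs, and overlay percentages are simple area ratios;
reports round half-up to two decimals while machine outputs keep raw
values.

## The synthetic study system

The generator emulates the statistical structure the analysis assumes, not
any real geography:

* **Covariates** are stationary Gaussian fields with exponential covariance
  (range 12 cells = 1.44 km at the default 120 m resolution), synthesized
  spectrally on the torus and standardized; land cover (natural,
  agriculture, urban, wetland, water) is carved from further fields and an
  elevation surface with a west-east gradient that dips below sea level, so
  inundation masks have coastline to bite.
* **The virtual species** is logistic in the covariates:
  $\text{suitability} = \text{logit}^{-1}(-8 + 6\,\text{greenness} -
  4\,\text{wetness} + 3\,\text{ruggedness})$. These defaults describe a
  sharp habitat specialist — about 9% of cells exceed suitability 0.9 —
  chosen once as the study condition for the recovery experiments. A
  weakly selective species would make every downstream accuracy bound
  unattainable for *any* method: a saturating logistic truth ties large
  fractions of presence-background pairs, capping even the true surface's
  AUC near 0.8.
* **Telemetry** is a biased random walk per animal: Gaussian step proposals
  (600 m scale) accepted by rejection sampling with probability
  proportional to the destination cell's truth suitability, which is the
  generating mechanism the parameter-recovery tests assume. Animals carry
  GPS (2-h cadence) or VHF (48-h cadence) collars; GPS fixes get lognormal
  DOP (median 2, $\sigma = 0.6$, leaving a nontrivial tail above the DOP
  > 7 screen) and DOP-scaled positional noise, VHF fixes a fixed 100 m
  error; records include juveniles, capture events and occasional
  mortalities so every screening rule has work to do.
* **Units** are a k-region Voronoi partition (default 4) — arbitrary but
  reproducible multiscale structure; **threat masks** are elevation
  thresholds (inundation), distance-decayed Bernoulli draws around urban
  seeds (development), and field-weighted Bernoulli draws over natural
  cells (protection).

What passing tests on this system do **not** show: real telemetry has
behavioral states, home-range fidelity, seasonal and sex structure, and
spatially structured observation failure, none of which are emulated; real
covariates have cross-correlations and anisotropies the generator lacks.
Accuracy achieved on the synthetic specialist is an upper bound on what an
equally sized real dataset would give, and the screening thresholds are
exercised, not validated, here.

## Numerical choices and degenerate inputs

* The distance transform is the exact separable lower-envelope-of-parabolas
  method, oracle-tested against the $O(n^2)$ brute force; distances are
  center-to-center ("Euclidean distance" in the standard GIS sense).
* Moving-window operations use disc neighborhoods of cell centers; edge
  windows renormalize by the in-extent cell count.
* Patches are 4-connected; perimeter counts exterior plus interior edges.
  The contiguity operator's window aggregation is this package's documented
  reading (3×3 template with orthogonal weight 2, diagonal 1, center 1,
  normalized so an isolated cell scores 0), since no formulaic definition
  exists in the workflow it emulates.
* KDE utilization distributions are binned kernel smooths with the
  reference bandwidth $h_{ref} = \sqrt{(\sigma_x^2+\sigma_y^2)/2} \cdot
  n^{-1/6}$; the "polygon" is the superlevel-set cell mask (no polygon
  geometry engine is involved anywhere: units, masks and regions are all
  label rasters, and raster interchange uses the plain-text ESRI ASCII grid
  format).
* Identical points (zero variance) are a bandwidth error; constant
  suitability surfaces are a Boyce error; zero-variance covariates are
  flagged degenerate and excluded from the correlation screen rather than
  crashing it; unparseable timestamps fail hard, naming the record.
* The sliding "12-month window" in screening is any 365-day window — the
  stricter faithful reading of an ambiguous rule — and the animal-level
  counts see only fixes that survived the fix-level screen. VHF fixes carry
  no DOP and are exempt from the DOP screen and from temporal subsampling.
  The fix-status codes treated as low quality default to `{2D, failed}`
  and are configurable, since no canonical code set exists.

## Problem sizes

Unit tests run on 60×60-cell landscapes with ~10 animals and oracle checks
on ≤ 20×20 grids; the end-to-end study and the acceptance script use the
full default conditions (200×200 cells at 120 m, 35 animals, 10-fold
cross-validation per extent, 10,000 background points per iteration). One
full run fits 2 × 10 models at the state scale plus 2 × 10 per unit and
completes in a few minutes on one CPU.

## Known limitations

* Maxent here is the L1-regularized Gibbs formulation with linear,
  quadratic and hinge features; it is not bit-compatible with the Java
  implementation (different optimizer, no product features, permutation
  importances instead of gain bookkeeping).
* The Mahalanobis family assumes an elliptical, unimodal niche; under a
  directional (logistic) truth it is systematically the weaker family, and
  the consensus inherits a fraction of that handicap — visible in the
  synthetic study exactly as in the real-data accuracy tables this package
  ships as worked examples.
* Background-as-negative-class evaluation bounds AUC away from 1 even for
  the true suitability surface; values are comparable across models, not
  absolute.
* The KDE background restriction applies to the state scale only; local
  extents sample background across their whole buffered unit. This mirrors
  the source workflow's treatment of spatial bias.

```{r example}
library(conshab)
run <- run_pipeline(run_config(seed = 1), out_dir = "run1")
print(run)           # held-out consensus accuracy, thresholds, areas
run$category$areas   # km^2 by habitat category
run$overlay          # threat/protection accounting
```
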