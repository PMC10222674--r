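---
title: "Methods: TSS-weighted ensemble distribution models and invasion risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS-weighted ensemble distribution models and invasion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

## The modelling problem

Species distribution models (SDMs) relate where a species has been
recorded to the environment at those places, under the equilibrium
assumption that occupied locations represent suitable environmental
space. `ensdm` implements the ensemble flavour of this workflow for
presence-only data: true absences are unavailable, so background
("pseudo-absence") points stand in for the negative class, several
algorithms are fitted repeatedly, and only skilful fits are combined.
The package adds an invasion-risk overlay: when a native species and an
invader are modelled on the same grid, the cellwise difference of their
suitability surfaces indexes where the invader is favoured.

## Protocol and parameters

The fitting protocol, with defaults in `esdm_config()`:

| stage | parameter | default | meaning |
|---|---|---|---|
| thinning | `thin_resolution` | landscape cell size | one record per fishnet cell |
| screening | `screen_threshold` | 0.7 | retain pairs with Pearson \|r\| < 0.7 |
| background | `n_pseudo_absences` | 5000 | uniform background points per set |
| background | `n_pa_sets` | 3 | independent background sets |
| split | `split_fraction` | 0.75 | training share, stratified by label |
| repetition | `n_repetitions` | 10 | re-draws of the split per set |
| learners | `algorithms` | RF, GBM, GLM | 3 × 10 × 3 = 90 single models |
| gating | `gate` | 0.9 | minimum held-out TSS for membership |
| classes | `class_thresholds` | 0.3, 0.5, 0.7 | suitability class boundaries |

Pseudo-absences are sampled uniformly from mask cells excluding
presence cells, without replacement within a set. The 75/25 split is
stratified by label with per-class `round()` counts. Each run is
evaluated on its held-out 25% only: AUC by the rank (Mann–Whitney)
formulation, and TSS maximised over all midpoints between consecutive
distinct scores (plus 0 and 1), ties broken toward the lower cutoff so
the optimum is exact and reproducible — a fixed grid can only do worse.
A score equal to the cutoff counts as predicted presence; that
boundary convention is arbitrary but must be fixed for reproducibility.

Members passing the gate are weighted by TSS, `W_i = a_i / Σ a_i`, and
the habitat suitability index of a cell is the weighted mean of member
probabilities — a convex combination, hence bounded by the member-wise
extremes and confined to [0, 1]. The ensemble's own skill is scored by
applying the weighted combination to the pooled held-out rows of all
members and re-optimising the cutoff; pooling is our choice (the
ensemble has no held-out set of its own) and is stated in the output
rather than hidden.

### Base learner settings

Hyperparameters are fixed, documented defaults, overridable through
`esdm_config(hyperparams = ...)`:

* **RF** — probability forest (`ranger`), 500 trees, `min.node.size`
  5, single-threaded with an explicit seed so predictions are
  bit-reproducible.
* **GBM** — gradient-boosted trees (`xgboost`), 500 rounds, learning
  rate 0.05, depth 3, no subsampling, exact (midpoint) split search.
  Exact splits matter here: histogram binning can throw a validation
  point lying just outside the training range onto the wrong side of a
  bin edge, which breaks the expectation that a separable table is
  classified perfectly.
* **GLM** — binomial logit with linear and quadratic terms per
  predictor, fitted by IRLS. Perfect separation halts IRLS early but
  the extreme fitted probabilities still rank correctly, so such fits
  are kept; only hard errors mark a run failed (failed runs are
  retained with a reason and excluded from gating).

Because 5000 background points typically outnumber presences several
fold, all learners weight the classes to equal total influence
(effective prevalence 0.5). Unweighted fits would push predicted
probabilities toward the background rate and distort the fixed class
thresholds; the protocol we follow is silent on this, so the weighting
is our documented choice.

The algorithm registry also names ANN, CTA, FDA, GAM, MARS and SRE,
which this protocol screens out by skill before ensembling; requesting
one raises a clear "not implemented" error rather than a silent fit.

### Seed management

A single master seed fans out deterministically to every stochastic
step (background set, split repetition, algorithm fit, permutation,
subsample) through a multiplicative hash kept below 2^31. Re-running
any stage with the same config reproduces its output exactly; no
global RNG state leaks between stages.

## Variable contributions and response curves

The contribution of a variable is permutation importance in the
biomod2 convention: 1 − Pearson r between ensemble predictions on the
original rows and on rows with that variable permuted, averaged over
permutations, capped at 1. A variable no member uses leaves predictions
bit-identical and scores exactly 0. Raw importances are normalised to
percentages, sorted descending, and accumulated; "key variables" are
the smallest leading set reaching 90% cumulative contribution. This is
the single largest methodological assumption in the package: the
upstream protocol never defines its contribution-rate algorithm, so we
state ours and keep it pluggable.

Response curves use the evaluation-strip method: sweep the focal
variable over its observed range (default 50 grid points) while other
variables keep their per-cell values on a seeded subsample of at most
10^4 mask cells, and average the ensemble prediction — a
partial-dependence-style mean response. The *best suitable range* is,
by default, the contiguous interval where the mean response is at
least half its maximum, which for a Gaussian truth response of breadth
σ has known endpoints (optimum ± σ√(2 ln 2)) and therefore supports
recovery tests. An absolute-level criterion (response ≥ 0.5) is
provided to probe sensitivity, since the derivation of published
"best suitable range" columns is typically unstated. Multimodal curves
return the qualifying interval containing the global maximum, flagged.

Note the scale caveat: the fitted mean response is a presence
probability against background, not the simulator's suitability on the
same scale; its half-max interval can shift by a grid step or so even
when the optimum is recovered exactly. Tests therefore check interval
recovery on constructed truth curves and optimum recovery on fitted
curves.

## Invasion risk

For co-registered suitability maps, `IRI = HSI_invader − HSI_native`,
antisymmetric and bounded in [−1, 1] by construction. Cells with
IRI > 0 (strict) are classed high-risk; the threshold is exposed
because published risk maps rarely state theirs, and 0 matches the
sign interpretation of the index. `fit_risk_regression()` runs
ordinary least squares of IRI on invader HSI per region with the
standard mean-response confidence band; a region with constant invader
HSI has an undefined slope and is reported as degenerate rather than
fitted. Fits use all region cells (counts are reported), not a
subsample.

## The virtual-species simulator

`make_landscape()` builds each layer as Gaussian-filtered white noise
standardised to mean 0, sd 1, mixed with a shared smoothed latent
field: `sqrt(c)·latent + sqrt(1−c)·noise` gives expected inter-layer
correlation `c`, so collinearity screening can be exercised at will.
Smoothing uses circular convolution (wrap-around edges are harmless in
synthetic fields). The "coastal" mask keeps a band of cells around a
smooth meandering curve to mimic a coastal strip. A niche is a product
of parametric response curves (Gaussian or logistic) rescaled to
maximum 1, which keeps truth in [0, 1] and makes half-max range
recovery well-posed; an optional prevalence target (fraction of mask
cells with truth ≥ 0.5) is met by a monotone power transform that
preserves optima. Presences are drawn without replacement with
probability proportional to truth; optional sub-cell jittered
duplicates exercise fishnet thinning. Prevalence and sampling bias are
parameters, not constants, because real surveys rarely report them.

What the simulator does *not* emulate: spatial sampling bias toward
accessible areas, observation error, dispersal limitation,
non-equilibrium dynamics, and interactions between variables beyond
the product rule. Passing recovery tests therefore shows the pipeline
recovers a knowable signal under its own assumptions — not that those
assumptions hold for any real coastline.

## Numerical and design choices

* Fishnet representative points use the cell-centre convention; if a
  coarse fishnet cell's centre falls off-mask, the surviving point
  nearest the centre represents the cell so no record is ever off the
  mask. Thinning is idempotent under a fixed resolution.
* Collinearity elimination is greedy on the largest violating |r|,
  dropping the lower-priority member (priority defaults to input
  order); the dropped pair and its r are recorded for audit. Constant
  layers (undefined r) are dropped up front with a warning.
* Rasters are exchanged as ESRI ASCII grids (`.asc`) with an explicit
  nodata value — a plain-text georeferenced format readable by common
  GIS tools — and occurrences as `species,x,y` CSV.
* Coordinates are x-east / y-north with half-open cells
  `[edge, edge + res)`; a point on a cell's low edge belongs to that
  cell, which makes cell assignment unambiguous.
* Layers must be pre-aligned; the package verifies co-registration
  (dimensions and masks) and never resamples or reprojects.

## Problem sizes in the test suite

The tests run the full 3 × 10 × 3 protocol with 5000-point background
sets on a 128 × 128 grid once, and a 20-replicate recovery study on
48 × 48 grids with 500 presences and compact single-set protocols.
These sizes give stable recovery statistics (truth correlation,
contribution ranking, ensemble-vs-member tendency) at desk scale; the
protocol itself is size-agnostic.

## Known limitations

* Pseudo-absence sampling is uniform; target-group or bias-corrected
  background sampling is not implemented.
* No spatial-block cross-validation: repeated random splits
  overestimate transferability when records are spatially clustered.
* The six screened-out learners are registry stubs by design.
* Confidence bands in the risk regression assume independent cells;
  spatial autocorrelation makes them optimistic for real rasters.
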