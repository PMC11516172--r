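---
title: "Methods: seasonal wildfire susceptibility and habitat overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal wildfire susceptibility and habitat overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firescape)
```

`firescape` models two probability surfaces per season — wildfire occurrence
risk and focal-species habitat suitability — from labeled point records and
environmental raster covariates, converts both to binary maps at the
threshold maximizing the true skill statistic (TSS), and overlays them to
account, in km², for habitat that is at risk of burning. This vignette
documents the modeling decisions, the tunable parameters, what the synthetic
landscape generator does and does not emulate, and the package's numerical
conventions.

## Data model

Rasters are matrices of cell values over a projected metric grid
(`raster_grid`), with `NA` as nodata; aligned layers form a `raster_stack`.
Alignment is validated, never repaired: resampling silently changes every
downstream statistic, so grids of different geometry are rejected. Points
are tibbles with `x`, `y` in projected meters plus `season`, `label` and
`source` columns. Geographic (degree) coordinate systems are rejected
because distance thinning and area accounting assume metric cells.
Point-to-cell lookup uses half-open intervals `[edge, edge + cell_size)` on
both axes: a point on a shared edge belongs to the cell to its right/below,
so every point has exactly one cell.

Files are exchanged as ESRI ASCII grid (`.asc`), a plain-text raster format,
with a JSON sidecar carrying the CRS tag and the class legend of categorical
grids. Continuous values are written at full double precision (round trips
are exact to well below 1e-9; integer grids are bit-exact). A raster without
its sidecar is refused rather than guessed at.

## Occurrence preparation

**Thinning.** Clustered occurrence points inflate spatial autocorrelation
and double-count detections. `thin_points()` keeps a point iff it lies at
least `min_distance` from every already-kept point, scanning in input order.
Greedy-by-order is deterministic and is the resolution rule implied by
standard GIS near-point filtering; a `shuffle_seed` argument permutes the
input first for sensitivity checks. Defaults follow the data sources being
emulated: 300 m for satellite fire detections (their detection resolution)
and 1000 m for field species records. When a `season` column is present,
thinning is per season — records from different seasons never exclude each
other, since each season is modeled separately.

**Correlation screening.** `correlation_screen()` iteratively removes one
member of the highest-|r| offending pair until no retained pair exceeds the
cutoff (0.75 for the fire covariates, 0.85 for the species covariates, both
overridable). Within a pair, the member with the larger mean |r| against all
other retained columns is dropped — keeping the more independent covariate —
with ties going to the later-named column. Constant columns have undefined
correlations; they are kept and flagged rather than silently removed.

**Landscape diversity.** `window_diversity()` computes, per cell, the
Shannon entropy of land-use class proportions in a centered window (default
5×5). The natural logarithm is used and declared here: with eight classes
the observed maxima (≈1.7–1.8) are consistent with either log base, so the
choice is a convention, not an inference. Edge windows are truncated;
nodata cells are excluded from the proportions; an all-nodata window yields
nodata. H is 0 exactly on monoclass windows and bounded by ln(K).

**Cross-tabulation.** `crosstab_landuse()` counts points per land-use class
and reports percentages as `100 * frequency / total`, rounded to two
decimals, with the denominator being the table's own total (per-season
tables use per-season totals). Points on nodata land-use cells are counted
in an explicit `unclassified` row. Reference frequency tables replayed in
the test suite contain a few rows whose printed percentages are
arithmetically inconsistent with their own frequency columns; the package
reproduces the arithmetic, not the misprints, and the tests skip those rows.

## Two-step pseudo-absence selection

Fire data are presence-only. The negative class is constructed in two steps:
presence-only models first delimit where fire plausibly occurs, and
pseudo-absences are then sampled outside that region.

Three presence-only members are fitted on a 70% training share of the
presences:

* **Climatic envelope** — suitable iff every covariate lies within the
  presence bounds at a percentile trim (default 0/100, the strict envelope;
  5/95 available for outlier-robust bounds).
* **Domain (Gower) model** — suitable iff the maximum Gower similarity
  `1 − mean_v |x_v − p_v| / range_v` to any training presence reaches θ
  (default 0.95, the conventional cutoff). Zero-range variables carry no
  information and are excluded with a warning.
* **One-class SVM** — an RBF-kernel novelty detector (ν = 0.1) on features
  standardized to the training mean/sd; deterministic under its seed.

Each member is scored by rank AUC on the held-out 30% of presences against
a uniform random background sample of equal size (for binary scores this
reduces to (sensitivity + specificity)/2). The background surrogate is a
design decision: the upstream workflow this package reimplements evaluates
its presence-only models on a 70/30 split without stating a negative class,
and random background is the standard stand-in. Members with AUC strictly
above the gate (default 0.8) are combined by majority vote with ties
resolved to 1. The tie rule is risk-conservative: it shrinks the
predicted-zero region rather than contaminating it with cells that half the
passing members consider at risk. If no member passes, the selection stops
with an error — pseudo-absences from an unvalidated zero region would be
meaningless — and on synthetic landscapes this happens on a minority of
realizations (roughly one in five at the default conditions), which the
reproduction script handles by drawing the next derived seed.

Pseudo-absences are sampled uniformly, without replacement, from zero-region
cells excluding any presence cell, at `multiplier` (default 2) times the
presence count, and placed at cell centers. No additional buffer around
presences is applied beyond zero-region membership.

## Classifier ensembles and AUC weighting

`split_table()` makes a label-stratified 70/30 train/test split.
`fit_suite()` fits every learner in a registry on the training part and
records its test AUC:

* `"fire6"`: random forest, classification tree, natural-spline-basis
  logistic regression, gradient-boosted trees, elastic-net-regularized
  logistic regression, plain logistic regression.
* `"sdm8"`: those plus a generalized additive model, a single-hidden-layer
  neural network, and an RBF-kernel SVM (and the GLM), for the species side.

Registries are pluggable (`learner_registry()` accepts a custom list), and
members that fail to fit are dropped with a warning rather than aborting
the suite; fewer than two survivors is an error. Learners run at library
defaults with fixed seeds — no hyperparameter tuning — because tuning is
not part of the workflow being reproduced. Class imbalance from the 1:2
presence:pseudo-absence design is left unweighted for the same reason.
Where the original toolchain uses proprietary learners, functionally
equivalent open implementations stand behind the same registry slots
(gradient-boosted trees for the boosted ensemble, the elastic-net path for
the regularization-path learner, a natural-spline logistic model for the
adaptive-spline learner).

The ensemble probability at a cell is the weighted mean `Σ w̃ᵢ pᵢ` with
`w̃ᵢ = AUCᵢ / Σ AUCⱼ` (raw AUC, not AUC − 0.5; `weight_mode = "auc_excess"`
exposes the alternative). The output is therefore bounded by the member
minimum and maximum everywhere, and nodata in any required layer propagates
to the prediction.

**Variable importance** is permutation-based on the test partition: fit the
bagged-tree learner, then for each variable average the drop in test AUC
over ≥10 random permutations of that column, floor negative drops at zero,
and normalize the weights to sum 1. Flooring means null-data weights are
noisy rather than uniform; the ranking, not the absolute weight, is the
interpretable quantity.

## Validation and thresholding

`auc_score()` is the rank-based (Mann–Whitney) AUC with ties counted ½,
computed from midranks — identical to exhaustive pairwise comparison, which
the test suite verifies on a thousand randomized small instances.
`tss_threshold()` searches the exact candidate set (midpoints of
consecutive sorted unique scores) for the TSS maximizer under the rule
`positive iff score ≥ threshold`; ties break toward the smallest threshold,
which maps more area as at-risk/suitable — the conservative direction for
conservation screening. All scores identical is an error (no informative
threshold exists). Validation reports carry AUC, threshold, sensitivity,
specificity, TSS = sensitivity + specificity − 1, and the
correct-classification rate (TP+TN)/N with its complement. The TSS column
is always the self-consistent function of the sensitivity and specificity
columns; external tables that print mutually inconsistent triples cannot be
reproduced and are not imitated.

## Seasonal change and GAP overlap

`change_index()` computes `|b − a| / max|b − a|` over cells valid in both
seasons. The index is symmetric, invariant to positive scaling of the
difference field, lies in [0, 1], and attains 1 somewhere unless the maps
coincide — in which degenerate case it is defined as identically 0. It is
produced for consecutive season pairs (spring→summer, summer→autumn).

`gap_overlap()` partitions aligned binary habitat and fire maps into
at-risk habitat (1,1), fire-only (0,1), habitat-only (1,0) and neither
(0,0), with areas `cells × (cell_size/1000)²`. Cells nodata in either input
are excluded from all four classes and reported separately, so the four
areas sum to the valid area exactly — a property the tests assert on random
masked grids.

## The synthetic landscape

`make_landscape()` generates the study conditions: per-season stacks of six
covariates (elevation, distance to road, land-surface temperature,
vegetation index, landscape diversity, heat load), a categorical land-use
map, and the true risk/suitability surfaces from which occurrences are
sampled.

Continuous fields are Gaussian-smoothed white noise (FFT convolution on the
torus) with a 16-cell correlation length, rescaled to ranges typical of
semi-arid mountain provinces: elevation 113–3317 m, heat load 0.3–1.12,
spring temperature 289.6–323.0 K shifted +16 K in summer and −5 K in
autumn, vegetation index ≈ −0.07–0.84 with small seasonal declines. The
temperature field is built anti-correlated with elevation (lapse-rate
structure, r ≈ −0.8) and the vegetation field positively correlated with it
(r ≈ +0.7): real covariates are collinear, and this is precisely what makes
the screening step meaningful — at the 0.75 fire cutoff one of the
elevation/temperature pair is typically removed, while both survive the
0.85 species cutoff. Distance to road is the Euclidean distance transform
of a random-walk polyline. Land use slices a second smooth field into
classes, then stamps agriculture preferentially at low elevation so fire
cross-tabulations concentrate in agricultural classes; the diversity layer
is the 5×5 entropy of that map.

True risk is `plogis(β₀ + Σ β·z)` on standardized layers. The default
coefficients (β₀ = −13; elevation −4, road distance −6, temperature +4,
vegetation +3, diversity +3, heat load +2) confine the fire-prone zone to
roughly 8% of the landscape. That sharpness is deliberate: satellite fire
detections are strongly clustered in reality, and a diffuse logistic
surface leaves the presence-only members below their own 0.8 AUC gate, so
the two-step design could never operate. The default species is a
vegetation-associated generalist (β₀ = −5; vegetation +3, mild positive
elevation and road-distance terms, diversity +1, heat load −1) whose
habitat partly overlaps the fire zone, which is the phenomenon the overlap
accounting exists to measure.

Presences are drawn without replacement with probability proportional to
the surface, at cell centers (no sub-cell jitter, keeping thinning tests
exact); a with-replacement mode exists for frequency tests. Identical spec
and seed give bit-identical landscapes.

**What the generator does not emulate:** fire spread and contagion, weather
and wind dynamics, sensor artifacts (scan-angle effects, cloud masks,
detection gaps), temporal autocorrelation between years, observer bias in
species records, and real road networks. Consequently, passing tests show
that the pipeline's statistics and bookkeeping are correct and that the
method recovers a known signal under favorable, well-specified conditions —
they do not certify performance on real satellite or field data, whose
printed validation values depend on inputs this package does not ship.

## Orchestration and reproducibility

`run_config()` collects every tunable with the study-design defaults
(thinning 300/1000 m; screening 0.75/0.85; gate 0.8; 2× pseudo-absences and
2× species background; 70/30 split; `fire6`/`sdm8` registries), optionally
overridden from YAML. `run_all()` executes the full per-season sequence,
writes plain-text rasters and CSVs, and a JSON manifest with the seed,
parameters, and per-stage record counts (points thinned, layers screened,
members gated, learners dropped). Every stochastic step draws from a seed
derived deterministically from the master seed, so rerunning a config
reproduces every output file bit-identically; the test suite asserts this
on file hashes. Default problem sizes — a 128×128 grid at 500 m with 300
presences per season for the fire side and the species side — were chosen
so a complete three-season study runs in well under a minute on one core
while leaving all estimators comfortably away from small-sample degeneracy;
module tests use 32–64-cell grids for speed.

## Known limitations

* The ensemble weights use raw AUC, so even chance-level members (AUC ≈
  0.5) retain weight; `auc_excess` is available but non-default.
* Presence-only member assessment against random background underestimates
  discrimination when presences cover much of the landscape; the gate then
  fails by design rather than silently accepting weak members.
* Greedy thinning depends on input order (documented, seedable); maximal
  independent-set thinning is deliberately not attempted.
* The binary-member AUC has coarse granularity at small test sizes, making
  the 0.8 gate a hard cliff for marginal members.
* Areas assume square metric cells; no geodesic correction is applied.
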