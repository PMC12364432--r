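---
title: "Methods: ensemble niche projection with dispersal and landscape constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche projection with dispersal and landscape constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carayaclim)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations of the pipeline. It states no empirical
result beyond what the test suite and the analysis scripts themselves
compute.

## The modeling chain

The pipeline projects climatically suitable area for a forest primate
(*Alouatta caraya*) from occurrence records and gridded bioclimatic
predictors, then asks how much of the projection the species can actually
reach and how fragmented the woody habitat inside it is.

**Occurrence cleaning.** Records beyond a 100-km buffer of the published
range polygon are dropped (`range_filter()`), and the survivors are thinned
to one per grid cell (`thin_one_per_cell()`). Where the original record per
cell is ambiguous the *first-encountered* record survives — a deterministic,
order-stable tie-break; exact duplicate coordinates (multi-database
compilations) are collapsed beforehand.

**Point design.** Background points characterise the accessible
environment: uniform random cells within the union of disks of radius
`hull_background_radius()` — the mean distance from the presence convex
hull's vertices to the hull centroid — around the presences, excluding
presence cells, 10 per presence by default (an absolute count, e.g. 10,000
for predictor screening, can override the multiplier). Congener records act
as absences after removing points within 100 km of the target range:
congeners are parapatric, so their verified presence elsewhere is the
closest available evidence of the target's absence. The two uses of the
background (screening vs. modeling) are independent calls; they share a
region but not necessarily a sample.

**Predictor screening.** On the background environment table, a greedy
stepwise VIF filter removes the largest-VIF variable while any VIF ≥ 9,
then a pairwise filter removes variables until all |r| < 0.6; within the
worst pair the member with the larger mean absolute correlation against the
remaining set is dropped, residual ties alphabetically. VIF before
correlation follows the order in which the two criteria are conventionally
stated; the composition is idempotent (re-screening the survivors changes
nothing), which the suite asserts.

**Models.** Two scorers ship natively under one contract (predict a
suitability in [0, 1] for a predictor row):

- *Bioclim envelope* (presence-only): per variable the presence mid-rank
  empirical CDF $F_v$ is stored; a query scores
  $\min_v\,\bigl(1 - |2F_v(x_v) - 1|\bigr)$ — 1 at the componentwise
  presence median, 0 outside the presence range. Min-aggregation is the
  classic envelope variant; a constant predictor degenerates to scoring 1
  at the constant and 0 elsewhere.
- *Ridge logistic regression* (presence–absence): IRLS maximising the
  Bernoulli log-likelihood minus $\tfrac{\lambda}{2}\lVert\beta\rVert^2$
  (intercept unpenalised), converged when the largest coefficient update
  falls below `tol`. The ridge (default $10^{-4}$) keeps complete
  separation finite. Congener absences and background points are pooled as
  the zero class — a declared assumption; the envelope ignores zeros.

Anything else — random forest, SVM, GAM, boosted trees, MaxEnt — enters the
ensemble through `plugin_model()`, which wraps an external scorer and
enforces the [0, 1] range. The package deliberately does not re-implement
those learners.

**Evaluation.** "Bootstrap" replicates are repeated stratified 70/30
subsamples *without* replacement (10 by default), matching the
train/test phrasing of the design rather than resampling with replacement.
Per replicate: AUC as the Mann–Whitney rank statistic (ties count half),
the max(se+sp) threshold chosen among midpoints of adjacent sorted unique
scores plus one candidate below and one above all scores (ties resolve to
the smallest maximiser), and TSS at that threshold. A replicate whose test
fold loses a class is redrawn (bounded retries).

**Ensemble and scenario consensus.** The consensus suitability is the
per-cell median across *all* replicate models of *all* algorithms (20 maps
for the two native algorithms × 10 replicates), not a median of
per-algorithm medians — with algorithms contributing equal replicate
counts the distinction only matters to tie patterns, and pooling keeps the
estimator a plain median. The binarisation threshold is max(se+sp) computed
on pooled per-row median predictions of all models over the full point
design, giving one coherent threshold per consensus map; future periods
have no observed labels, so they reuse the present threshold. Futures are
combined GCM-first (per-cell median of the per-GCM ensemble maps for one
SSP and period), binarised, then SSP-second as a 2-of-3 vote: occupied iff
the mean of the three SSP votes is ≥ 0.34, which is exactly the per-cell
majority rule (asserted exhaustively on all 8 vote patterns). The order
median → binarise → vote was one of several defensible readings; it is
fixed here and recorded on every output map.

**Dispersal.** The maximum dispersal distance per generation follows the
home-range allometry $\mathrm{MDD}_1 = 40\sqrt{\mathrm{HR}\cdot 10^4}$ m
with HR in hectares; over an interval it scales linearly with the whole
number of generations (non-integer generation counts are rejected with
guidance). At the defaults (HR = 11.875 ha, 10-year generations) this gives
13,784 m per generation and 27,568 m per 20-year interval. Reachability is
straight-line: a future cell stays occupied iff it is suitable and its
centre lies within the interval MDD of a previously occupied cell centre,
via an exact two-pass Euclidean distance transform
(Felzenszwalb–Huttenlocher), chained interval by interval from the present
consensus map. Seeding from the present *consensus* map (rather than from
occurrence buffers) is a declared choice: it keeps the dispersal stage a
function of the model chain alone. No cost surface is applied.

**Landscape metrics.** Woody fragments are 4-connected (rook) components —
matching how standard GIS raster polygonisation separates diagonal
contact — with raster-edge ("staircase") perimeters; FI = Σarea/Σperimeter
is therefore resolution-dependent, which is why `fragmentation_index()`
also accepts pre-summed totals from external tables. Fragments below the
11.875-ha minimum home range are discarded. Connectivity is the mean over
fragments of the mean centroid distance to all other fragments — identical
to the mean over ordered pairs (and hence to unordered pairs), so the
ordered/unordered question is moot for this symmetric mean.

**Area accounting.** maintained = area(p1 ∩ p2), lost = area(p1 \ p2),
gained = area(p2 \ p1), through a per-cell area grid (uniform on planar
grids; cosine-latitude-corrected on geographic ones). Two percentage
conventions are explicit parameters, never implicit: `P1_ALL` divides all
three by the period-1 area; `P1_MAINT_LOST_P2_GAIN` divides the gain by the
period-2 area instead (a gain is then expressed relative to the range it
enlarges). Both appear in published change tables, which is precisely why
the convention is declared per report. Refuges are the cellwise
intersection of the present and all future consensus maps; protected-area
overlap is computed on the rasterised grid (consistent with all other area
math — sub-cell slivers are below the model's resolution anyway).

## Parameter defaults

| parameter | default | units | role |
|---|---|---|---|
| VIF threshold | 9 | — | collinearity screen |
| abs. correlation threshold | 0.6 | — | pairwise screen |
| replicates / train fraction | 10 / 0.7 | — | evaluation design |
| SSP vote threshold | 0.34 | — | 2-of-3 consensus |
| range buffer | 100 | km | occurrence cleaning |
| congener exclusion | 100 | km | absence trimming |
| background multiplier | 10 | points/presence | point design |
| home range | 11.875 | ha | dispersal allometry, minimum fragment |
| generation time / interval | 10 / 20 | years | dispersal accumulation |

`default_config()` carries exactly these values and a single test asserts
them, so any deviation in a run is a deliberate, visible config edit.

## The synthetic data generator

The generator produces every input with known ground truth so the chain is
testable without downloads. What it emulates, and how:

- **Climate layers** are smoothed white noise (separable truncated-Gaussian
  kernel, sd = `spatial_scale` cells, radius 3×, edge-renormalised) plus a
  linear gradient in a random direction, standardised to mean 0, sd 1.
  This reproduces the two features the pipeline is sensitive to — spatial
  autocorrelation and broad gradients — and nothing else.
- **Futures** are additive shifts on named layers. In the demo the shifts
  grow with period and scenario severity, differ slightly between the two
  synthetic GCMs, and push the niche-favoured layers away from the
  species' optimum (the quadratic-response layer is shifted so the optimal
  band *moves*, producing both losses and gains).
- **Presences** are rejection-sampled on cell centres with acceptance
  probability equal to a logistic niche (linear + optional quadratic
  terms) — cell-centre granularity matches the one-per-cell thinning
  downstream. The demo uses 3% of the cell count (300 on the default
  100 × 100 grid), which leaves room for the 10× background sample.
- **Land cover** grows a scheduled number of woody patches to a scheduled
  woody fraction; different patches may touch diagonally but never share a
  rook edge, so the 4-connected patch count equals the schedule exactly
  and the fraction is met cell-exactly (both well inside the ±10%/±20%
  tolerances the generator promises).
- **Protected areas** are disjoint random rectangles packing a target
  fraction of the grid (11% in the demo).

Synthetic grids are planar and equal-area (map units km; one cell =
cell_size² km²), isolating algorithmic correctness from projection issues;
geographic inputs are supported via haversine distances (Earth radius
6,371 km) and cosine-latitude cell areas, but the tests exercise the planar
path. What the generator does *not* emulate: climate physics, realistic
bioclimatic covariance structure, observation bias in occurrences, or
curvilinear grids — so green tests certify the algorithms, not the ecology
of any real landscape.

## Numerical conventions and edge cases

- Suitability maps are clipped to [0, 1]; nodata (NA) propagates through
  prediction, ensembling (a consensus cell is nodata if any input is) and
  binarisation.
- The even-count median is the mean of the central pair.
- `binarize()` uses ≥, so threshold 0 marks every valid cell suitable.
- The empirical CDF of the envelope is the mid-rank variant
  $(\#\{s<x\} + \tfrac12\#\{s=x\})/n$, making the presence median score
  exactly 1 and ties behave symmetrically.
- The distance transform replaces "no source" with a finite sentinel larger
  than any in-grid squared distance, keeping the parabola intersections of
  the two-pass transform well defined; an all-empty map returns Inf.
- Degenerate inputs fail loudly: empty range polygons, all-nodata rasters,
  single-class labels, non-integer generation counts, infeasible land-cover
  schedules and protected-area packings are all rejected with messages.
- All randomness flows from one root seed through named substreams
  (`child_seed`), so identical seeds give byte-identical summaries and any
  stage can be reproduced in isolation.

## Problem sizes used by the suite

The suite runs the full demo twice at 100 × 100 cells (determinism check)
and smaller pipelines at 40 × 40; oracle-equivalence checks use 50 random
instances each; statistical properties use 10 seeds (logistic coefficient
recovery within ±15% at n = 2,000; informative-variable importance ranked
first; FI non-increasing under a fragmenting schedule). These sizes were
chosen so the whole suite completes in about a minute while keeping every
statistical check comfortably powered.

## Known limitations

- Only two scorers ship natively; ensembles mixing plugin learners inherit
  whatever calibration those learners have.
- Raster-edge perimeters make FI resolution-dependent; compare FI values
  only within one resolution, or feed pre-summed totals.
- Straight-line reachability ignores resistance; a cost-surface dispersal
  model would need a different clipping stage.
- The dispersal stage seeds from the modeled present range, not from
  observed occupancy; where the model over-predicts the present, reach is
  over-generous.
- Geographic-grid support (haversine, cosine-latitude areas) is exercised
  by unit tests only at closed-form checkpoints, not by an end-to-end
  geographic pipeline run.
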