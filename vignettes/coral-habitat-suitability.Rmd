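---
title: "Methods: presence-background habitat suitability modelling for deep-sea corals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background habitat suitability modelling for deep-sea corals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep-sea corals are vulnerable marine ecosystem engineers whose
distribution across a continental margin is known only at a scatter of
surveyed points.  `coralhsm` implements an end-to-end pipeline that turns
heterogeneous raw inputs — scattered bathymetric soundings, depth-binned
ocean climatology volumes, opportunistic coral presence records, fishery
logbook trawl lines, protected-area polygons and a substrate
classification — into cross-validated habitat suitability maps and
management-oriented overlap tables, entirely on a planar 500 m analysis
grid.

Because the real inputs are large, proprietary, or both, the package
ships a first-class synthetic seascape generator with known ground truth;
every stage of the pipeline is validated against that truth or against
independent oracles.

## The model

The core is a from-scratch maximum-entropy presence-background model.
Given presence cells and a background sample of available environment,
the fitted distribution over background cells is the Gibbs form

$$q_\lambda(x) = \frac{\exp\left(\sum_j \lambda_j f_j(x)\right)}{Z_\lambda},$$

where the features $f_j$ are linear, quadratic, product and hinge
transforms of the environmental layers, rescaled to $[0,1]$ on the
background.  The weights minimize the L1-regularized negative average
presence log-likelihood; at the optimum the defining moment property
holds: $|E_q[f_j] - \bar f_j| \le \beta_j$, with equality where
$\lambda_j \ne 0$.  The optimizer is cyclic coordinate descent with
per-coordinate Newton steps, soft-thresholding for the L1 penalty, and
step-halving so the objective never increases; iteration stops when a
full sweep improves the objective by less than the convergence threshold
(default `1e-5`, cap 500 sweeps, regularization multiplier 1 — the
conventional defaults for this model family).

Map output uses the logistic habitat suitability index
$\mathrm{HSI} = e^H q(x) / (1 + e^H q(x))$ with $H$ the entropy of the
fitted distribution; under the null model the HSI is exactly 0.5
everywhere, so 0.5 marks "typical" presence conditions.  Variable
importance is reported by a jack-knife: for each variable, the
regularized training gain of the model without it and of the model on it
alone, plus the held-out AUC of the latter.

### Regularization

$\beta_j = r \cdot \hat\sigma_j(\text{presences}) \cdot c(m)$, where $r$
is the regularization multiplier (default 1), $\hat\sigma_j$ is the
presence standard deviation of the feature (floored at $10^{-4}$), and
$c(m)$ interpolates the published default table by feature class over
the presence count $m$, divided by $\sqrt m$.  Feature classes follow
the standard sample-size rule: linear always, quadratic from $m \ge 10$,
hinge from $m \ge 15$ (knots at background deciles), product from
$m \ge 80$.

## Spatial cross-validation and consensus

Presences are partitioned into four spatial regions.  Each fold trains
on three regions and scores the held-out region's presences against a
study-wide background sample (10,000 cells by default, presences merged
in).  Test AUC is the normalized rank-sum statistic — the probability
that a presence outranks a random background cell, ties credited one
half — with a bootstrap standard deviation over test presences
(100 replicates) and a two-sided rank-sum significance test (normal
approximation with tie correction, no continuity correction).  Folds
with AUC strictly above 0.7 are retained; retained folds are thresholded
at 0.5 and 0.75 (strictly greater) and summed into consensus grids
valued 0..K, K the number of retained folds.

Without explicit boundaries the partition defaults to quadrants at the
presence median easting/northing, with split-line ties to the
lower-index region.  The synthetic seascape additionally emits four
along-shore bands as its stated cross-validation geography: the analysis
this pipeline reimplements partitions along the coastline, so every
region spans the full shelf-to-basin habitat gradient.  Quadrants on a
margin whose suitability gradient runs west-east would instead hold out
environmentally disjoint areas — a transferability experiment, not the
intended sampling-bias check.

## Layer construction

**Bathymetry.** Soundings are cleaned (non-finite, non-positive-depth
and out-of-extent points dropped with an audit), gridded by per-cell
median over half-open 500 m footprints, and infilled by
nearest-neighbour resampling of a coarse reference grid (block means at
2 km by default, standing in for satellite-altimetry products).  The
median replaces a spline gridder deliberately: it is deterministic,
dependency-free, robust, and no downstream statistic depends on
interpolator smoothness.  Slope uses Horn's 8-neighbour gradient; for
windows above one cell the grid is block-mean aggregated to the window
resolution, Horn is applied there, and values are assigned back to
constituent cells.  Horn is exact on planes at every window, which the
tests exploit.  Both window sets mentioned in the source material
({1, 5, 10, 20} km and {0.5, 1, 2.5, 5, 20} km) are supported; neither
is hard-coded.

**Climatology up-scaling.** Each depth bin of a climatology volume is
IDW-interpolated (power 2, 8 neighbours — the method is named in the
source, the parameters are ours) to an intermediate resolution (5 times
coarser than the bathymetry by default), nearest-neighbour resampled to
the analysis grid, and clipped to the band of seafloor whose depth is
nearest that bin's standard level.  Bin membership uses
midpoint-bounded nearest-level intervals with ties to the shallower
level; depths beyond the deepest level clamp to the deepest bin rather
than dropping to no-data, so the mapped domain never silently shrinks.
The per-cell source bin is recorded and the assignment is a partition —
both tested invariants.  Layers are validated against water-bottle
casts filtered to post-2001 collection, a bottom-depth flag, and sample
depth within 5% of the local bathymetry; the report gives Pearson r and
r-squared with per-filter exclusion counts.

**Variable pruning.** Pairwise Pearson correlations above 0.7 are
resolved by dropping the non-protected member (later-listed when both
are droppable); depth, temperature and carbonate-saturation analogs can
be protected jointly, in which case their pairs are exempt.

## Presence quality control

Four rules, applied in a fixed order so each record carries one primary
removal reason: (1) bottom-trawl bycatch; (2) depth strictly less than
50 m (a record at exactly 50 m survives); (3) family-level taxonomy
unknown; (4) spatial duplicates — at most one record per taxon (order
or suborder) per 500 m cell.  The duplicate survivor is the first
record after a deterministic sort by (source, x, y, depth); for
presence-only modelling the choice is inert since only cell occupancy
enters the model, but the audit requires determinism.  Rule 2 uses the
recorded depth by default with a switch to bathymetric depth.  Taxon
sets below 50 records (configurable; the source material brackets the
bar between 30 and 128) are flagged unmodelable.

## Overlap accounting

Zonal statistics count cells whose **centers** fall inside a polygon
(no partial-cell weighting), report areas in km² and nm²
(1 nm² = 3.429904 km²), and summarize the share of suitable (consensus
> 0) area.  Substrate cross-tabulations resample the finer substrate
grid by majority rule (ties hard > mixed > soft) and report the
substrate composition of each consensus class.  Trawl intensity is the
summed clipped length of line segments within a 3 km disc of each cell
center divided by the disc area (km of line per km²), with cells
masked when fewer than three distinct vessels contribute — the privacy
rule of fishery logbook products.  Niche summaries report per-variable
ranges, percentiles, fractions within half-open user ranges, and a
kernel density trace for bean-plot style display.

## The synthetic seascape

The generator states a complete world once; its defaults are the
conditions the tests then probe.

- **Bathymetry**: a linear shelf-to-basin ramp (30–3000 m west to
  east) plus three Gaussian canyon incisions deepening seaward, six
  Gaussian seamounts spread across all depths, and smoothed noise
  (15 m), clipped to [10 m, 3000 m].  Spreading seamounts across the
  extent keeps steep terrain from being confined to the cold deep end.
  Survey tracks (straight lines with jitter) accumulate until 35% of
  cells hold a sounding (the stated coverage of the reimplemented
  bathymetry); soundings carry 5 m noise.
- **Climatology**: temperature $2 + 8e^{-z/300}$ °C, salinity
  monotone increasing, oxygen with a minimum centered at 1700 m; each
  on a 10-times-coarser grid with a small centered horizontal trend and
  per-cell noise.
- **Truth suitability**: logistic in standardized layers with weights
  temperature −3, slope +3, depth −5 and intercept −2.  The negative
  temperature and depth weights give the cold-water azooxanthellate
  niche an interior depth optimum: warm shallow water and the abyssal
  plain are both unsuitable, and the suitable band sits on the
  mid-depth slope where canyon walls and seamount flanks are steep.
  That geometry is what produces the qualitative substrate pattern
  (hard-ground share rising with suitability class) and matches why a
  50 m shallow cutoff exists at all.
- **Presences**: sampled over cells with probability proportional to
  suitability$^\gamma$, $\gamma = 3$; with a negative-intercept
  logistic this approximates presence intensity log-linear in the
  environment — the canonical presence-background simulation design —
  and yields fold-level test AUCs in the 0.7–0.9 range the real
  datasets of this kind exhibit.  A bias polygon (an intensively
  surveyed canyon analog) multiplies sampling weight by
  `1 + sampling_bias_strength` (default 2).  Contaminants are appended
  at stated rates: trawl-gear records jittered up to 2 km, shallow
  (< 50 m) records, unknown-family records, and exact duplicates; all
  carry hidden truth labels that the analysis ignores and the QC tests
  use as an answer key.
- **Overlays**: two rectangular and one circular sanctuary analog; a
  5-times-finer substrate grid whose hard-ground probability is
  logistic in the local slope percentile (`plogis(-3.5 + 5 rk)` — hard
  is the minority class overall but dominates the steepest
  percentiles); trawl segments concentrated shelf-ward, tagged with one
  of 12 vessels; and the four along-shore cross-validation bands.

What the generator does **not** emulate: oceanographic circulation,
seasonal variability, geodetic coordinates, positional error structure
by gear, taxonomic misidentification beyond the unknown-family class,
and spatial autocorrelation of residual noise.  A green end-to-end test
therefore establishes that the pipeline recovers a known
environment-driven niche through realistic data plumbing — not that it
would reproduce any particular real-world map.

## Numerical choices and edge cases

- Half-open cell footprints everywhere; a point on the grid's outer
  east/north edge is out of extent.
- "Exact" reproduction claims (piecewise-constant climatology, null
  model HSI = 0.5) are asserted to machine rounding (1e-12): IDW's
  weighted mean of identical values and the entropy/normalizer
  round-trip each accumulate one ulp-level rounding.
- The sensitivity+specificity threshold is reported as the midpoint of
  the optimal open interval between adjacent observed scores; the 10th
  percentile of training HSI uses the nearest-rank definition.
- Degenerate inputs: empty sounding sets are legal; extrusion of an
  empty field, IDW with no valid sources, thresholds outside (0,1),
  non-positive cell sizes and unknown keep-list names all raise errors.
- Seeds: every generator derives a deterministic sub-seed per sub-task,
  so outputs are byte-identical per master seed and adding a generator
  never perturbs another.

## Design choices where the ground was open

- **Null-model sanity test.** The "random presences give AUC ≈ 0.5"
  check runs on a seascape with zero horizontal climatology gradients
  so that the four regions are environmentally exchangeable.  With
  trended covariates a spatially held-out region is distinguishable in
  environment space even under a presence-environment null, and spatial
  cross-validation is then conservative by construction (fold AUCs
  systematically off 0.5); the exchangeable null isolates the property
  actually being tested.
- **Study-wide background** for fold scoring (switchable to held-out
  region only), since the source procedure does not restrict background
  regionally.
- **Bootstrap SD** (100 reps over test presences) for the test-AUC
  standard deviation, which the source reports without defining.
- **Coarse infill at 2 km** block means: comparable to the resolution
  of global altimetry-derived products that fill sounding gaps in real
  workflows.  Nearest-neighbour infill makes terrain derivatives over
  infilled areas blocky, which is why slope recovered from sparse
  soundings is a weak single-variable predictor in the synthetic world
  even though slope helps the generative truth — a faithful artifact,
  noted rather than hidden.

## Known limitations

- No geodesy: planar metres only, equal-area cells by construction.
- Raster exchange is ESRI ASCII text (no GeoTIFF binding available in
  the supported dependency set); GeoJSON covers polygons and polylines.
- The optimizer targets the KKT moment property, not bit-parity with
  any historical Java implementation; threshold-class features and
  cloglog output are out of scope.
- The substrate cross-tab trend is asserted as "top class harder than
  class 0" — the qualitative "generally increased" pattern — not as
  strict monotonicity across every intermediate class.
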