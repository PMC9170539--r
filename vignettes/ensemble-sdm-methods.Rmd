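---
title: "Methods: performance-weighted ensemble SDMs with climate-predictability predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: performance-weighted ensemble SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmensemble)
```

## The modelling problem

Occurrence archives give presences only. To fit a classifier one needs
contrast — points standing in for absence — and how those pseudo-absences
(PAs) are chosen shapes the whole model. `sdmensemble` implements the
presence/pseudo-absence ensemble design used widely for invasive and
cultivation-candidate species: a climate envelope fitted to presences
defines "climatically plausible", PAs are drawn outside it, and a set of
tree-ensemble classifiers fitted across PA realizations and repeated data
splits is combined by predictive performance.

The pipeline assumes the species is environment-limited rather than
dispersal-limited, so occurrence records from the full (native plus
introduced) range can be pooled and the fitted surface read as an estimate
of the fundamental climatic niche. Where that assumption fails, the maps
describe the realized record distribution instead — the machinery is the
same, the interpretation is not.

## Grid and nodata conventions

All rasters share one convention: square lon/lat cells (WGS84 degrees),
cell (1, 1) in the north-west corner, and half-open cells
`[edge, edge + cell_size)` so a point on a shared edge belongs to the cell
to its south/east. Every point-to-cell operation (thinning, extraction,
PA placement) uses `floor((coord − origin) / cell_size)`, so there is
exactly one answer to "which cell is this point in".

Nodata is `NA` in memory and is handled by masking, never by sentinel
arithmetic: any operation with a nodata operand yields nodata, a stack's
valid mask is the intersection of its layers' masks, and no value is ever
imputed. Rasters are exchanged as ESRI ASCII grids (plain text, 17
significant digits, so round trips are bit-exact); monthly precipitation
series as directories of `YYYY-MM.asc` files. Inputs are expected in
lon/lat WGS84; there is no reprojection machinery, deliberately.

Bilinear resampling interpolates between the four surrounding source cell
centers with weights renormalized over valid neighbours; a target cell
whose whole support is nodata stays nodata, and values are clamped to the
source hull so output never leaves the source `[min, max]`. Nearest-cell
resampling serves categorical or binary layers. The collinearity screen
reports pairwise Pearson correlations (default advisory threshold
`|r| >= 0.7`, a conventional rule of thumb, configurable) but drops
nothing — predictor choice is a modelling decision, not a side effect.

## Derived climate predictors

**Annual totals.** A calendar year contributes at a cell only if all 12
months are valid there ("complete year"); incomplete years are dropped per
cell, not globally, which preserves coverage at the edges of a record.

**Hellmann–Eberle quotient.** `Q = max_y P_y / min_y P_y` over a cell's
complete-year totals, a measure of inter-annual rainfall unpredictability:
`Q >= 1`, with `Q = 1` only for perfectly regular rainfall, and `Q`
invariant to rescaling all years by a positive constant. At least two
complete years are required. A driest year of exactly 0 mm is masked
rather than mapped to infinity: downstream learners need a finite ratio
map, and at climate-record resolution an all-dry year cannot be told from
a data gap.

**Ellenberg index.** The binary flag `mean_annual < 500 mm AND Q > 5`
marks regions where low rainfall coincides with unpredictable rainfall —
conditions under which stem succulents are typically absent despite
aridity. The mean annual precipitation over complete years is used for the
500 mm test; both thresholds are parameters (`ellenberg_params()`).

**Aridity and R indices.** `AI = P/PET` and `R = AET/PET`, both masked
where `PET <= 0`. PET and AET are consumed as input layers (the synthetic
module fabricates them); computing them from first principles
(Penman–Monteith) is out of scope. `AET > PET` warns but passes through —
the index deliberately does not launder its inputs.

## Occurrences

The validity filter drops missing/out-of-range coordinates, the exact
`(0, 0)` sentinel, and coordinate duplicates beyond a cap (lowest
record IDs kept, so the result is deterministic). The full location-based
cleaning protocols used on real archives (institution coordinates, country
centroids, sea tests) are intentionally not reimplemented; the reduced
filter set is small enough to inspect.

Thinning retains at most 5 records per 1° × 1° cell (both configurable),
on a lattice anchored at integer degrees — the natural reading of a
one-degree graticule. Within an over-full cell the retained records are
chosen uniformly at random under a seed rather than first-n: first-n would
silently encode the archive's sort order. Thinning is idempotent and never
invents records.

## Pseudo-absence design

The surface range envelope is fitted on **all** thinned presences (not the
60% training split): the envelope is part of the sampling design, not of
any individual model, and fitting it once keeps the five PA realizations
exchangeable. Its per-variable bounds are the `q` and `1 − q` empirical
quantiles with linear interpolation between order statistics (R's type 7)
— the quantile level alone does not pin down an estimator, so the
estimator is fixed for reproducibility. Default `q = 0.025` trims the
extreme 2.5% per tail; `q = 0` reduces to the presence min/max, and the
envelope shrinks monotonically as `q` grows.

Eligible background cells are valid in every predictor, outside the
envelope, and not occupied by any presence (so no cell ever carries both
labels). Each realization samples its cells uniformly without replacement
and places PAs at cell centers; realizations are independent via derived
sub-seeds. Uniform-over-cells is the default reading of "from all areas
outside"; latitude-area-weighted sampling is available behind a flag. The
number of PAs equals the number of presences (the equal-n design keeps TSS
and ROC comparable across scenarios), and five realizations is the
default, reducing dependence on any single unlucky background draw.

## Learners, splits, ensembles

Two algorithms are fitted — boosted classification trees (xgboost) and
random forests (randomForest) — as pluggable `fit`/`predict-probability`
learners; the contribution of this package is the surrounding design, not
tree induction. Defaults are deliberately plain: 500 trees (forest);
200 rounds, depth 3, learning rate 0.1, subsample 0.8 (boosting); both
single-threaded so fits are bitwise reproducible under their seed.

Each run splits its dataset 60/40, stratified by label — stratification
preserves the engineered 1:1 class balance in both partitions — with a
fresh split per repeat (repeats that shared a split would only measure
learner noise). All scores are computed on the held-out 40% only. The full
design is 2 algorithms × 5 PA realizations × 10 repeats = 100 runs per
ensemble, 500 across the five predictor scenarios; the test suite
exercises a scaled 2 × 2 × 2 configuration with identical bookkeeping.

Ensemble weights are proportional to the member's TSS (ROC selectable),
with negative TSS clamped to 0 and members at ROC AUC ≤ 0.5 — no better
than random — excluded outright (strict inequality). Proportional-to-metric
is this package's documented choice among the several weighting rules in
circulation. The ensemble map is the per-cell convex combination of member
maps; the uncertainty map is the per-cell coefficient of variation,
`100 · sd/mean`, using the unweighted sample (n−1) standard deviation
across members — "coefficient of variation of the member probabilities"
names no weighting, so none is applied.

Ensemble-level scores use pooled held-out evaluation: every run's test
rows are predicted with the full weighted-mean ensemble and the pooled
prediction/label pairs are scored once. Pooling (rather than averaging
per-realization scores) evaluates the object actually published — the
single weighted ensemble — on rows none of which the scored prediction's
"own" member saw at training time in its split.

## Evaluation and the binary cutoff

`TSS = sensitivity + specificity − 1` (prevalence-insensitive, unlike
kappa, which is deliberately not provided); ROC AUC is the Mann–Whitney
probability of ranking a presence above an absence, ties at one half. The
binary cutoff maximizes sensitivity + specificity over the data-adaptive
candidate set — midpoints between adjacent distinct predictions plus
{0, 1} — which finds the exact optimum; ties break to the smallest cutoff.
A prediction exactly at a cutoff counts as a presence everywhere in the
package (evaluation and map binarization share the `>=` convention).
Scores are kept at full precision internally; the 3-decimal rounding seen
in report tables happens only in the CSV writer.

## Permutation variable importance

For each predictor: permute its column in the reference table (default 10
shuffles), re-predict with the ensemble, and compute the Pearson
correlation `r` with the unshuffled predictions. Raw importance is the
mean of `max(0, 1 − r)`. The direction matters and is easy to get
backwards: the *correlation* is high when a predictor does not matter
(shuffling changed nothing), so "0 means no influence" can only describe
`1 − r`, which is what is implemented. Only the lower side is clamped;
`r < 0` yields raw importance above 1 and is passed through to
standardization, `percent = raw / sum(raw) × 100`. Importance is computed
on the pooled reference table (presences once, plus every realization's
PAs); per-member-then-average is a configurable alternative.

## Area accounting and scenario comparison

Cell areas use a spherical Earth, `R = 6371 km`:
`A = R² · Δλ · (sin φ_top − sin φ_bottom)` — exact on the sphere, constant
along a row, and summing to `4πR²` on a global grid. At the
three-significant-figure precision of million-km² summaries, ellipsoidal
refinement changes nothing. Suitable area is the masked sum of cell areas
over the binary map; deviation maps are signed differences of continuous
suitability between a scenario and the bioclim-only baseline, with a
gain/loss/stable binary variant.

## The synthetic study system

`recovery_fixture()` is the desk-scale stand-in for a global 2.5-arcmin
analysis: a 64 × 64 grid (0.5° cells over a 32° window), four smooth
mutually correlated predictors (Gaussian-filtered noise, correlation
length 6 cells, pairwise correlation 0.3 — enough to make importance
attribution non-trivial without collinearity dominating), a truth in which
the minimum temperature of the coldest month acts through a steep rising
logistic (midpoint 5 °C, slope 1.5 /°C — a hard cold limit, the
physiological signature of frost-sensitive succulents) and annual
precipitation through a broad Gaussian (center 800 mm, width 500 mm — a
secondary, unimodal control), 500 presences drawn with probability ∝
suitability × a lognormal effort field (collection bias for thinning to
correct), jittered within cells so no convention is exercised only at cell
centers. Monthly rainfall generators use lognormal annual totals (median =
the requested mean-annual, log-sd the variability control): non-negative,
right-skewed like rainfall, with closed-form control of `Q`'s behaviour;
totals are spread over months by a cosine seasonal profile. Cells are
independent across the rainfall simulation — spatial smoothness is not
needed for the quotient's statistics, only marginal variability is.

What the fixture does *not* emulate: the spatial covariance structure of
real climate normals, topographic gradients, spatially autocorrelated
observation error, or taxonomic noise. Passing the recovery tests
therefore shows the pipeline's statistical machinery is sound — it does
not certify performance on any real archive.

Tests and the acceptance script run the 2 × 2 × 2 scaled design on this
fixture (about ten seconds end to end), a size chosen so the whole suite
re-runs casually during development; the bookkeeping logic is identical at
the full 2 × 5 × 10 design, whose counts are asserted arithmetically.

## Reproducibility

A single master seed fans out to every random stage (thinning, PA
realizations, splits, learner seeds, importance shuffles) through
`derive_seed(master, stage, indices...)`, a 31-bit string-fold hash —
stages get decoupled streams, and a scenario rerun with the same master
seed is byte-identical down to its CSV and raster outputs. No package
function disturbs the caller's RNG state (`withr::with_seed` throughout).

## Known limitations

- Presence/pseudo-absence TSS and AUC are computed against *constructed*
  absences drawn outside the envelope; they measure separation from that
  background, and are optimistic relative to evaluation against true
  absences.
- Importance is per-predictor marginal; correlated predictors share credit
  and interactions are not decomposed.
- No spatial cross-validation: splits are random over rows, so spatial
  autocorrelation inflates held-out scores on strongly clustered data.
- Only lon/lat WGS84 rasters; only the two tree-ensemble learners; no
  future-climate projection workflow.
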