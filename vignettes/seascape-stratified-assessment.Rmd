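---
title: "Seascape-stratified reserve assessment: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seascape-stratified reserve assessment: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seascapeCI` tests marine-reserve effects while controlling for seascape
heterogeneity. This vignette is the package's own account of the science
inside it: the models and their assumptions, the parameters that matter,
the numerical and design choices made where the method left them open,
and what the synthetic validation does and does not demonstrate.

## The assessment model

The analysis unit is a patch reef site with a zone label (reserve or
control) and six community responses: fish species richness, total and
commercially-targeted fish biomass (allometric `a L^b` conversion of fork
lengths, summed per species per survey cylinder, then averaged over all
cylinders), stony-coral richness, percent coral cover from point-intercept
image scoring, and the coral:macroalgal cover ratio (turf and crustose
coralline algae excluded).

A pooled Control-Impact assessment is a one-way ANOVA of each response on
zone over all sites. The stratified assessment first classifies sites into
seascape groups and tests the zone contrast only within a group. Both are
reported side by side; the package's central claim — demonstrated by
simulation, not assumed — is that when reserve responses differ in sign or
magnitude between seascape types, the pooled contrast loses or cancels
signal that the stratified contrast retains.

ANOVAs run on variance-stabilizing scales: log10(x + 1) for biomass,
richness and ratio responses, arcsine-square-root for percent cover. The
+1 offset only matters for empty sites and is negligible at observed
magnitudes (biomasses of order 10^3 g). Percent effect sizes are always
computed from the *raw* zone means, under both reporting conventions:
`100 (in − out)/out` ("X% greater inside than outside") and
`100 (in − out)/in`. Published reserve contrasts mix the two conventions,
and they differ materially for large effects, so every effect row carries
both and a direction flag; sign always agrees with `in − out`.

## Metric selection: CCA with an AIC surrogate

Candidate seascape metrics are transformed (log10 for distances, areas
and perimeter; Box-Cox for the edge:area ratio and bathymetric volume,
with the power fitted by profile likelihood on a λ grid over [−3, 3] in
0.01 steps; untransformed otherwise), then standardized to zero mean and
unit variance. Standardization is a deliberate choice: canonical
coefficients are otherwise scale-dependent, and whether to standardize is
exactly the kind of detail assessments rarely state.

Collinearity is screened with Pearson correlations: metrics joined by
|r| > 0.2 edges form blocks by transitive closure (connected components),
and each block is replaced by the first principal component of its
correlation matrix, sign-anchored to the block's first member. Be aware
that transitive closure at a threshold as permissive as 0.2 can merge
broadly: on strongly type-structured seascapes (including the default
simulator, where the latent type imprints on nearly every metric) most
metrics join a single block whose PC1 is essentially the seascape-type
axis, and selection then operates on that composite. On field data with
weaker global structure the blocks are smaller — typically the six
patch-size metrics (area, hard-substrate area, perimeter, edge:area,
rugosity-scaled volume, bathymetric volume) collapsing to one
`patch_size` axis.

The community table is related to metrics by canonical correspondence
analysis in its classical chi-square form: with relative abundances `P`,
row/column weights `r`, `c`, the standardized residual matrix
`Q = (P − r c')/sqrt(r c')` has total inertia `sum(Q²)` equal to the
table's chi-square statistic over its grand total; `Q` is projected by
weighted least squares onto the standardized metrics and the fitted
matrix decomposed by SVD. Two non-obvious aspects:

* **CCA on summary responses.** The ordination runs on three summary
  variables per community (richness and two biomasses; richness, cover,
  ratio), not a full species table. That is unusual for CCA but is the
  assessment design this package implements; the chi-square machinery
  only requires a nonnegative table with positive row sums, which these
  summaries satisfy. For the same reason the responses enter CCA
  untransformed — log-transformed values can be negative, which the
  chi-square framework forbids.
* **AIC for constrained ordination has no canonical definition.** Forward
  selection uses the residual-inertia surrogate
  `AIC = n ln(residual inertia / n) + 2(k + 1)`, stopping when no
  candidate lowers it; candidates whose addition makes the design matrix
  rank-deficient (duplicates, aliased dummies) are skipped. The surrogate
  is declared and swappable; nothing downstream depends on its absolute
  value, only on the selected set, and the validation requires only that
  a planted three-metric model is recovered in simulation.

Model significance uses simple row permutation of the environmental
matrix (exact under site exchangeability), with
`p = (1 + #{F_perm ≥ F_obs}) / (n_perm + 1)`; 999 permutations give a
p-value floor of 0.001.

## Classification and community tests

Sites are clustered on the selected standardized metrics with Euclidean
distance and Ward linkage (`ward.D2`), cut at k = 2. The method names
neither a linkage nor a distance; Ward is the default because it produces
compact, balanced groups and therefore workable within-group sample
sizes, which is the point of stratifying; the linkage is an argument, not
a constant. Group labels are ordered by descending group mean distance
from channel, so "Type I" is always the group further from channels.
Merge-height ties fall back on `hclust`'s deterministic lowest-index
behaviour.

Community-level zone and type effects use Clarke's ANOSIM on Bray-Curtis
dissimilarities of fourth-root transformed abundances. Bray-Curtis is a
semimetric — the triangle inequality can fail — so no metric property is
asserted anywhere. The two-way crossed form re-ranks dissimilarities
within each level of the other factor, averages the per-level R
statistics, and permutes labels only within those levels; with a single
level it reduces exactly to one-way ANOSIM (a property the tests check
against an independent implementation). For n = 6 the one-way permutation
distribution is enumerated exhaustively rather than sampled.

The species-level screen runs per-species ANOVAs within each seascape
group at α = 0.05 with no multiple-testing correction — deliberately
faithful to common assessment practice; a Benjamini–Hochberg option
exists (`p_adjust = "BH"`) but is off by default. Expect ~1 false
positive per 20 null species per group, and read the screen as
hypothesis generation.

## The synthetic seascape and observation model

The generator emulates a reef lagoon of the kind these assessments are
run on: a 2000 × 2000 m lagoon at 4 m raster resolution, ~95
non-overlapping elliptical patch reefs with areas log-uniform on
20–10,000 m², a lagoon floor sloping 6–18 m with patch tops rising to
0.5–3 m below the surface, two channel passes on the rim, a mangrove
stand, and a no-take reserve covering the western 35% of the lagoon.
Reserve membership is spatial (a sector polygon), not randomized per
site, so zone is partially confounded with seascape gradients exactly as
in real reserve placements.

Two latent seascape types are planted by construction. Type II patches
sit in annuli around the channels in dense arrays, are drawn from the
small end of the area range (20–1,000 m²), and carry high structural
complexity and fine rugosity; Type I patches occupy the open lagoon at
least 700 m from channels with a 160 m minimum spacing (isolation),
drawn large (800–8,000 m²), dome-shaped and smoother. Three structural
choices keep the planted confounding *balanced* rather than degenerate:
the type and home channel of each patch are fixed before placement (so
rejection sampling cannot skew composition), channels inside the reserve
receive annulus area proportional to the Type I reserve share (so the
types have equal zone composition in expectation), and each channel's
annulus area scales with its weight (so Type II local density — hence
nearest-neighbor and buffer covariates — is zone-symmetric).

Observations follow the survey protocol: per species and cylinder, fish
counts are Poisson with a log link on standardized covariates (distance
from channel, log10 reef area in the 500 m buffer, log10 nearest
neighbor), a lognormal site effect (σ = 0.30), and a reserve effect
applied only inside the reserve and only to the configured type; fork
lengths are lognormal and convert to biomass allometrically (coefficients
are config inputs — the values used by field studies are citation-bound
and not reproducible, so none are hard-coded). True coral and macroalgal
covers are logit-normal with covariates (patch size, distance from
channel, structural complexity); point-intercept scores are multinomial
draws of 100 points on each of 20 images per site. Poisson counts and
lognormal lengths are the simplest forms with the monotone covariate
dependence the assessment presumes; no density dependence, movement or
temporal dynamics are modelled.

Default planted effects reproduce a mixed-sign response pattern on the
Type II / Type I axis: commercial fish biomass ×1.75 and non-commercial
×1.25 inside the reserve on Type II only (total biomass ≈ ×1.5), coral
cover ×0.35 on Type I but ×1.68 on Type II, coral richness ×0.83 on Type
II, and macroalgal shifts that move the coral:macroalgal ratio roughly
−57%/+80%. The covariate coefficients and baselines (coral cover ≈ 0.14
on Type I and ≈ 0.27 on Type II control sites) were fixed once, by pilot
simulation, so that the two coral-cover effects approximately cancel in
the pooled arcsine-scale contrast — the masking regime the stratified
design exists for — and were not revisited afterwards.

One global seed drives everything; each stage (placement, bathymetry,
surveys, each permutation stream) derives an independent child seed, so
stages can be re-run or replicated independently and every stochastic
result records its seed.

## Numerical choices and degenerate inputs

* **Patch delineation** uses 8-connectivity (diagonally touching reef
  cells are one patch), configurable to 4; ids are stable under
  row-major ordering of first cells.
* **Perimeter** is the unsmoothed cell-edge boundary length (exposed
  edges × cell size). This over-estimates smooth outlines by a staircase
  factor (up to √2 for diagonal edges); the bias is documented rather
  than corrected, because hand-digitized reference outlines are not
  reproducible. Areas are cell counts × cell area; geometry therefore
  always carries physical units, never pixels.
* **Edge:area ratio** is perimeter/area (units 1/m) by default. Published
  summary values for this metric are not always consistent with that
  formula, so the ratio accepts any `function(perimeter, area)`.
* **Buffer reef area** dilates the focal patch by the radius using
  centre-to-centre cell distances, counts reef cells whose centres fall
  inside, and excludes the focal patch's own cells ("reef area *around*
  each reef"); inclusion is a flag. Buffers reaching past the raster
  edge are computed on the available extent and flagged `truncated`.
* **Bathymetric volume** integrates (reference − depth) over patch cells
  against a local lagoon-floor reference equal to the maximum depth in a
  3-cell ring around the patch — the reference depth is otherwise
  undefined on a sloping floor. Surface area uses central-difference
  slopes (one-sided at raster edges); on a hemispherical bump it
  converges to 2πr² from below at roughly the square root of the cell
  size, which is why the validation uses a fine grid and a 5% tolerance.
* **Coarse rugosity** walks the two principal-axis chords through the
  patch centroid in cell-size steps, accumulating
  `sqrt(cell² + Δdepth²)`; single-cell patches return 1 with a warning;
  the index is invariant to chord direction.
* **Nearest neighbor** is centroid-to-centroid ("a center point within
  each patch polygon"), not edge-to-edge; a single patch yields NA with
  a warning, never 0.
* **Distance to features** is the minimum over feature points, in km.
* **Zeros under log/Box-Cox**: transforms fail naming the offending
  positions unless an explicit offset is given; the environmental-matrix
  builder uses half the smallest positive value when a column contains
  zeros (buffer areas of isolated patches).
* **All-zero response columns** are dropped from CCA with a warning;
  rank-deficient environmental matrices fail naming the aliased columns;
  an all-zero site pair gets Bray-Curtis 0 with a warning.

## The power experiment and its calibration

`power_experiment()` repeats the full simulate → metrics → cluster →
assess cycle (fresh seascape each replicate by default) and reports, per
response, the rejection rate of the pooled contrast and of the stratified
design. The stratified *decision* per replicate is the minimum
Bonferroni-adjusted p across tested strata. This is a deliberate
departure from "any stratum significant at α": with two strata the naive
rule rejects ~9.8% of null replicates, and a power comparison against a
pooled test of size 5% would be rigged. With the Bonferroni combination
both designs reject at ≈ α under a null simulation (a property the test
suite verifies with 500 null replicates), so any stratified advantage
under planted effects is real. Per-stratum report tables still show raw
p-values at α = 0.05, as assessments conventionally do.

Within the power loop, clustering uses the configured fish metric set
(distance from channel, 500 m buffer reef area, nearest neighbor) and the
coral set (distance from channel, patch-size PC1 over the collinear size
block, structural complexity) rather than re-running AIC selection each
replicate; selection is validated separately, and fixing the sets keeps
the experiment about the *stratification*, not about selection
variability.

Problem sizes used by the validation suite are the package's chosen
compromise between Monte-Carlo stability and desk-scale runtimes: 200
replicate cycles for the masking experiment, 200 null replicates × 199
permutations for permutation-test calibration, 500 survey-level
replicates for ANOVA size, 100 replicates for selection recovery, 50
scenes for type recovery, 20 random rasters (≤ 100×100 cells) for the
brute-force oracle equivalences.

## What passing tests do and do not show

The synthetic validation demonstrates internal correctness and the
masking phenomenon under the generator's assumptions: independent Poisson
counts, logit-normal covers, static communities, exactly two latent
types with clean metric signatures, and reserve effects that switch on at
the boundary polygon. Real seascapes differ in ways the generator does
not emulate: habitat maps carry classification error; fish move across
zone boundaries (edge effects and spillover blur the contrast); community
covariance is richer than independent per-species draws; seascape types
are rarely discrete; and reserve effects accrue over time rather than
existing as fixed multipliers. Passing tests therefore validate the
*machinery* and the *logic* of stratified assessment — they do not
certify that any particular field system has recoverable types or
effects of the planted magnitude. The species-level screen is
uncorrected by design and should be read accordingly.

BACI-style designs with pre-designation data are out of scope, as are
spectral classification of imagery, geodesic coordinate handling (all
coordinates are planar metres) and mechanistic trophic models.
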