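# seascapeCI

Seascape-stratified Control-Impact assessment of marine reserves.

## The problem

No-take marine reserves are most often evaluated with Control-Impact (CI)
comparisons: community metrics at sites inside the reserve are compared
with control sites outside, and the difference is read as the management
effect. In a heterogeneous seascape this logic breaks down. Patch reefs
differ in size, structure, isolation and position relative to channels and
mangroves, those differences drive fish and coral communities directly,
and reserves are never placed at random — so seascape variation is
confounded with protection and can mask real reserve effects (or
manufacture spurious ones). When reserve responses differ in sign between
seascape types, a pooled CI contrast can cancel to nothing while strong
effects exist within every type.

`seascapeCI` implements, end to end, a landscape-ecology remedy for users
who assess reserves on patch-reef (or similar patchy) seascapes:

1. **Quantify seascape heterogeneity** — per-site configuration metrics
   (distance from channels and mangroves, nearest-neighbor distance, reef
   area in 200 m / 500 m / 1 km buffers), composition metrics (area,
   hard-substrate area, perimeter, edge:area ratio, rugosity-scaled and
   bathymetric volumes, 3-D surface area) and structure variables (fine
   and coarse rugosity, ordinal structural complexity) from a categorical
   habitat raster, a bathymetry grid, vector features and in-situ surveys.
2. **Select the metrics that matter** — transform (log10 / Box-Cox /
   arcsine-sqrt), standardize, screen collinearity at |r| > 0.2, collapse
   collinear blocks to their first principal component, and relate the
   community table to candidate metrics by canonical correspondence
   analysis (CCA) with AIC forward selection and Monte-Carlo permutation
   tests (999 permutations).
3. **Classify sites** — Ward hierarchical clustering of the selected,
   standardized metrics into seascape groups (k = 2 by default).
4. **Assess the reserve within groups** — one-way ANOVA reserve-vs-control
   contrasts pooled and per group, percent effect sizes under both
   baseline conventions, two-way crossed ANOSIM on Bray-Curtis
   dissimilarities of fourth-root abundances, and a species-level
   response screen.

Because the motivating field data are not public, the package ships a
first-class synthetic seascape generator (`generate_seascape()`,
`simulate_communities()`) that emulates a reef lagoon: ~100 elliptical
patch reefs of 20–10,000 m² on a 4 m habitat grid, a sloping 6–18 m
lagoon floor with patch tops near the surface, a reserve occupying one
sector, and two latent seascape types whose reserve responses differ in
sign and magnitude. Every downstream stage is tested against this
generator and against brute-force oracles.

## Core quantities

- CCA total inertia equals the chi-square statistic of the community
  table divided by its grand total; the constrained share is obtained by
  weighted least-squares projection of the standardized residual matrix
  `Q = (P - rc') / sqrt(rc')` onto the environmental matrix, with
  pseudo-F `= (constrained/k) / (residual/(n-k-1))`.
- Bray-Curtis dissimilarity `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`
  on fourth-root transformed abundances.
- ANOSIM `R = (mean between-group rank - mean within-group rank) /
  (n(n-1)/4)`, with ranks computed within levels of the crossing factor
  for the two-way design.
- Reserve effect size `100 (mean_in - mean_out) / mean_out` (outside
  baseline) and `100 (mean_in - mean_out) / mean_in` (inside baseline).

## Worked example

```r
library(seascapeCI)

cfg    <- sim_config(rng_seed = 1)        # default study conditions
scene  <- generate_seascape(cfg)
metrics   <- seascape_metrics(scene)
survey    <- simulate_communities(scene, metrics, cfg)
responses <- summarize_responses(survey, cfg$species)
report <- assess_reserve(metrics, responses,
                         species_biomass = species_biomass_matrix(survey, cfg$species),
                         n_perm = 999, seed = 1)
report
#> <assessment_report> 87 sites | fish metrics: distance_from_channel_km_PC1+distance_to_mangroves_km | coral metrics: distance_from_channel_km_PC1
#>   significant contrasts: pooled 0, stratified fish 2, stratified coral 5 (alpha = 0.05)

subset(report$stratified_fish,
       response == "fish_total_biomass_g" & stratum == "Type II",
       c(n_in, n_out, p_value, pct_diff_outside))
#>   n_in n_out p_value pct_diff_outside
#> 1   13    42 0.01028            34.23

subset(report$stratified_coral, response == "coral_cover_pct",
       c(stratum, n_in, n_out, p_value, pct_diff_outside))
#>   stratum n_in n_out   p_value pct_diff_outside
#> 1  Type I   10    22 4.868e-06           -56.20
#> 2 Type II   13    42 1.096e-05            40.63
```

The pooled contrast detects nothing — zone means are nearly equal because
the Type I coral decline cancels the Type II gain and the fish effects are
diluted — while the stratified tables recover the planted mixed-sign
pattern: fish biomass higher inside the reserve on Type II patches only
(+34% realized for this seed against a planted +50% total and +75%
commercial effect), coral cover +41% inside on Type II but −56% on Type I.
On strongly type-structured scenes the |r| &gt; 0.2 collinearity screen
merges most metrics into one block, so the selected
`distance_from_channel_km_PC1` composite is essentially the seascape-type
axis itself. `power_experiment()` repeats the
whole simulate → metrics → cluster → assess cycle to quantify exactly how
much detection power the pooled design loses; `proportional_difference()`
reproduces printed percent contrasts from group means (e.g. coral
richness means of 17.4 outside and 14.9 inside give −17% under the
inside-baseline convention).

`run_pipeline()` executes the full chain and persists every intermediate
artifact (ASCII-grid rasters, GeoJSON features, CSV tables, a versioned
JSON report and a checksummed manifest), and can resume any stage from
the persisted files.

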