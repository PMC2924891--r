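# Survey-level replication on a fixed scene keeps these calibration
# experiments cheap: the seascape, metrics and clusters are computed once
# and only the observation layer is redrawn.
null_config <- function(...) {
  tiny_config(
    n_patches = 40, n_sites = 32,
    species = default_species_table(10, 4),
    delta_fish = list(commercial = c(type1 = 0, type2 = 0),
                      noncommercial = c(type1 = 0, type2 = 0)),
    delta_coral_cover = c(type1 = 0, type2 = 0),
    delta_coral_richness = c(type1 = 0, type2 = 0),
    delta_macroalgae = c(type1 = 0, type2 = 0),
    beta_fish = c(distance_from_channel_km = 0, reef_area_500m_m2 = 0,
                  nearest_neighbor_m = 0),
    beta_coral = c(patch_size = 0, distance_from_channel_km = 0,
                   structural_complexity = 0),
    ...)
}

survey_pvals <- function(cfg, scene, met, groups, response, reps, seed0) {
  vapply(seq_len(reps), function(i) {
    sv <- simulate_communities(scene, met, cfg, seed = seed0 + i)
    resp <- summarize_responses(sv, cfg$species)
    sites <- site_records(resp, groups$fish, groups$coral)
    comm <- if (grepl("^fish", response)) "fish" else "coral"
    st <- stratified_ci(sites, comm, responses = response)
    ps <- st$p_value[st$tested]
    c(pooled = pooled_ci(sites, response)$p_value,
      stratified = if (length(ps)) min(pmin(ps * length(ps), 1)) else NA)
  }, c(pooled = 0, stratified = 0))
}

test_that("with all reserve effects off, pooled and stratified tests
           reject at about the nominal level", {
  cfg <- null_config()
  scene <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(scene, buffers = 500))
  env <- build_env_matrix(met)
  groups <- seascapeCI:::power_groupings(env, met, 2)
  ps <- survey_pvals(cfg, scene, met, groups, "fish_total_biomass_g",
                     reps = 500, seed0 = 40000)
  ci <- qbinom(c(0.025, 0.975), 500, 0.05) / 500
  expect_gte(mean(ps["pooled", ] < 0.05), ci[1] - 1e-9)
  expect_lte(mean(ps["pooled", ] < 0.05), ci[2] + 1e-9)
  # Bonferroni-combined stratified decision is calibrated (if slightly
  # conservative) as well
  expect_lte(mean(ps["stratified", ] < 0.05), ci[2] + 1e-9)
})

test_that("power decreases monotonically as the planted coral effect
           shrinks to zero", {
  rates <- sapply(c(1, 0.4, 0), function(s) {
    cfg <- tiny_config(
      n_patches = 40, n_sites = 32,
      delta_coral_cover = c(type1 = s * log(0.35), type2 = s * log(1.68)))
    scene <- generate_seascape(cfg)
    met <- suppressWarnings(seascape_metrics(scene, buffers = 500))
    env <- build_env_matrix(met)
    groups <- seascapeCI:::power_groupings(env, met, 2)
    ps <- survey_pvals(cfg, scene, met, groups, "coral_cover_pct",
                       reps = 100, seed0 = 61000)
    mean(ps["stratified", ] < 0.05, na.rm = TRUE)
  })
  expect_gte(rates[1], rates[2] - 0.05)
  expect_gte(rates[2], rates[3] - 0.05)
  expect_gt(rates[1], 0.8)
  expect_lt(rates[3], 0.12)
})

test_that("shuffling group labels collapses stratified power toward pooled", {
  cfg <- tiny_config(n_patches = 40, n_sites = 32)
  scene <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(scene, buffers = 500))
  env <- build_env_matrix(met)
  groups <- seascapeCI:::power_groupings(env, met, 2)
  shuffled <- groups
  withr::with_seed(5, {
    shuffled$fish$group <- sample(shuffled$fish$group)
    shuffled$coral$group <- sample(shuffled$coral$group)
  })
  p_true <- survey_pvals(cfg, scene, met, groups, "coral_cover_pct",
                         reps = 100, seed0 = 71000)
  p_shuf <- survey_pvals(cfg, scene, met, shuffled, "coral_cover_pct",
                         reps = 100, seed0 = 71000)
  pow <- function(m) mean(m["stratified", ] < 0.05, na.rm = TRUE)
  expect_gt(pow(p_true), pow(p_shuf) + 0.2)
})

test_that("power_experiment returns a complete, attribute-rich table", {
  pw <- suppressWarnings(power_experiment(tiny_config(n_patches = 25,
                                                      n_sites = 20),
                                          n_replicates = 6, seed = 3))
  expect_s3_class(pw, "power_table")
  expect_equal(sort(unique(pw$design)), c("pooled", "stratified"))
  expect_equal(nrow(pw), 12)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  pv <- attr(pw, "p_values")
  expect_equal(dim(pv$pooled), c(6, 6))
  expect_length(attr(pw, "ari"), 2)
})
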