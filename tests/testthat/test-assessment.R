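# a compact synthetic site table with controllable effects
make_sites <- function(n_per_cell = 8, effect_t2 = 0, effect_t1 = 0,
                       sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(zone = c("reserve", "control"),
                        grp = c("I", "II"), i = seq_len(n_per_cell),
                        stringsAsFactors = FALSE)
    base <- 10
    eff <- ifelse(grid$zone == "reserve",
                  ifelse(grid$grp == "II", effect_t2, effect_t1), 0)
    tibble::tibble(
      site_id = sprintf("s%03d", seq_len(nrow(grid))),
      zone = grid$zone,
      fish_group = factor(grid$grp), coral_group = factor(grid$grp),
      fish_total_biomass_g = base * exp(eff + rnorm(nrow(grid), 0, sd)))
  })
}

test_that("opposite-sign effects cancel pooled but not stratified", {
  sites <- make_sites(n_per_cell = 12, effect_t2 = log(1.6),
                      effect_t1 = -log(1.6), sd = 0.08, seed = 3)
  pooled <- pooled_ci(sites, "fish_total_biomass_g")
  strat <- stratified_ci(sites, "fish", "fish_total_biomass_g")
  expect_gt(pooled$p_value, 0.05)
  # multiplicative +-60% effects leave only the arithmetic-mean remainder
  expect_lt(abs(pooled$pct_diff_outside), 20)
  expect_true(all(strat$p_value < 0.01))
  expect_lt(strat$pct_diff_outside[strat$stratum == "Type I"], -30)
  expect_gt(strat$pct_diff_outside[strat$stratum == "Type II"], 30)
})

test_that("a single group makes the stratified contrast identical to pooled", {
  sites <- make_sites(effect_t2 = log(1.4), seed = 4)
  sites$fish_group <- factor("I")
  pooled <- pooled_ci(sites, "fish_total_biomass_g")
  strat <- stratified_ci(sites, "fish", "fish_total_biomass_g")
  expect_equal(nrow(strat), 1)
  expect_equal(strat$F, pooled$F)
  expect_equal(strat$p_value, pooled$p_value)
  expect_equal(strat$n_in + strat$n_out, pooled$n_in + pooled$n_out)
})

test_that("stratum sample sizes partition the pooled n and df follow strata", {
  sites <- make_sites(n_per_cell = 7, seed = 5)
  pooled <- pooled_ci(sites, "fish_total_biomass_g")
  strat <- stratified_ci(sites, "fish", "fish_total_biomass_g")
  expect_equal(sum(strat$n_in) + sum(strat$n_out),
               pooled$n_in + pooled$n_out)
  expect_equal(strat$df2, strat$n_in + strat$n_out - 2)
})

test_that("empty stratified cells become explicit untested gap rows", {
  sites <- make_sites(seed = 6)
  sites$zone[sites$fish_group == "II"] <- "control"
  strat <- stratified_ci(sites, "fish", "fish_total_biomass_g")
  gap <- strat[strat$stratum == "Type II", ]
  expect_false(gap$tested)
  expect_match(gap$note, "insufficient")
  expect_true(strat$tested[strat$stratum == "Type I"])
})

test_that("effect signs agree with mean ordering in both conventions", {
  sites <- make_sites(effect_t2 = log(2), sd = 0.05, seed = 7)
  strat <- stratified_ci(sites, "fish", "fish_total_biomass_g")
  t2 <- strat[strat$stratum == "Type II", ]
  expect_equal(sign(t2$pct_diff_outside), sign(t2$mean_in - t2$mean_out))
  expect_equal(sign(t2$pct_diff_inside), sign(t2$mean_in - t2$mean_out))
  expect_equal(t2$direction, "inside_higher")
})

test_that("species screen flags planted responders and guards absences", {
  withr::with_seed(9, {
    n <- 40
    zone <- rep(c("reserve", "control"), each = n / 2)
    groups <- factor(rep("II", n))
    base <- matrix(rexp(n * 6, 1 / 50), n, 6,
                   dimnames = list(NULL, sprintf("sp%02d", 1:6)))
    base[zone == "reserve", 1:2] <- base[zone == "reserve", 1:2] * 6
    base[, 6] <- ifelse(zone == "reserve", 0, 30)  # absent from one zone? no:
    base[zone == "reserve", 5] <- 0                # absent inside
    biomass <- tibble::as_tibble(base)
    biomass$site_id <- sprintf("s%02d", 1:n)
  })
  out <- species_response_screen(biomass, groups, zone)
  expect_true(all(out$significant[out$species %in% c("sp01", "sp02")]))
  sp5 <- out[out$species == "sp05", ]
  expect_false(sp5$testable)
  expect_false(sp5$significant)
})

test_that("full assessment report is assembled with every site in one
           stratum per community", {
  cfg <- tiny_config(n_patches = 30, n_sites = 24)
  sc <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(sc))
  sv <- simulate_communities(sc, met, cfg)
  resp <- summarize_responses(sv, cfg$species)
  bio <- species_biomass_matrix(sv, cfg$species)
  rep <- suppressWarnings(assess_reserve(met, resp, species_biomass = bio,
                                         n_perm = 49, seed = 2))
  expect_s3_class(rep, "assessment_report")
  expect_equal(nrow(rep$sites), nrow(resp))
  expect_equal(sum(table(rep$sites$fish_group)), nrow(resp))
  expect_equal(sum(table(rep$sites$coral_group)), nrow(resp))
  expect_equal(sum(rep$pooled$n_in + rep$pooled$n_out) / nrow(rep$pooled),
               nrow(resp))
  # stratified totals partition pooled n for each response
  for (tab in list(rep$stratified_fish, rep$stratified_coral)) {
    agg <- tapply(tab$n_in + tab$n_out, tab$response, sum)
    expect_true(all(agg == nrow(resp)))
  }
  expect_s3_class(rep$anosim, "anosim_result")
  expect_true(all(c("grouping", "block") %in% rep$anosim$factor) ||
                "grouping" %in% rep$anosim$factor)
})
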