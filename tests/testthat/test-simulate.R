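test_that("allometric conversion matches closed forms and a power oracle", {
  expect_equal(allometric_biomass(10, 0.01, 3), 10)
  L <- c(7.3, 21.8); a <- 0.024
  expect_equal(allometric_biomass(L, a, 1), a * L)
  # high-precision scalar oracle: exp(log a + b log L)
  expect_equal(allometric_biomass(23.5, 0.0105, 3.05),
               exp(log(0.0105) + 3.05 * log(23.5)), tolerance = 1e-12)
  expect_error(allometric_biomass(-1, 0.01, 3), "positive")
  expect_error(allometric_biomass(10, 0, 3), "positive")
})

test_that("an empty scene (n_patches = 0) still yields valid rasters", {
  cfg <- tiny_config(n_patches = 0)
  sc <- generate_seascape(cfg)
  expect_equal(nrow(sc$patches), 0)
  expect_equal(nrow(sc$sites), 0)
  expect_true(all(sc$habitat$values %in% c(1L, 2L)))
  expect_true(all(sc$bathymetry$values >= 0))
  expect_equal(dim(sc$habitat$values), dim(sc$bathymetry$values))
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- tiny_config(n_patches = 50, n_sites = 30,
                     type1_area_range_m2 = c(200, 1500),
                     type2_area_range_m2 = c(20, 300))
  s1 <- generate_seascape(cfg)
  s2 <- generate_seascape(cfg)
  expect_identical(s1$habitat$values, s2$habitat$values)
  expect_identical(s1$bathymetry$values, s2$bathymetry$values)
  expect_identical(s1$patches$x, s2$patches$x)
  s3 <- generate_seascape(tiny_config(n_patches = 50, n_sites = 30,
                                      type1_area_range_m2 = c(200, 1500),
                                      type2_area_range_m2 = c(20, 300),
                                      rng_seed = 12))
  expect_false(identical(s1$habitat$values, s3$habitat$values))
})

test_that("rasterized patch areas respect the configured range up to
           one row/column of discretization error", {
  cfg <- sim_config(n_patches = 200, n_sites = 20, rng_seed = 5,
                    lagoon_width_m = 3000, lagoon_height_m = 3000)
  sc <- generate_seascape(cfg)
  cs <- cfg$cell_size_m
  raster_area <- sc$patches$n_cells * cs^2
  # per-patch slack: one cell row plus one column across the bounding box
  slack <- cs * (4 * sc$patches$semi_major) + 4 * cs^2
  expect_true(all(raster_area >= pmax(0, sc$patches$area_m2 - slack)))
  expect_true(all(raster_area <= sc$patches$area_m2 + slack))
  expect_true(all(sc$patches$area_m2 >= cfg$patch_area_range_m2[1] - 1e-9))
  expect_true(all(sc$patches$area_m2 <= cfg$patch_area_range_m2[2] + 1e-9))
})

test_that("true patches map 1:1 onto connected reef components", {
  sc <- generate_seascape(tiny_config())
  dl <- delineate_patches(sc$habitat)
  expect_equal(nrow(dl), nrow(sc$patches))
  # every true cell set is exactly one delineated component
  key <- vapply(dl$cells, function(cc) paste(sort(cc), collapse = ","), "")
  for (i in seq_len(nrow(sc$patches)))
    expect_true(paste(sort(sc$patches$cells[[i]]), collapse = ",") %in% key)
  # bathymetry is shallower over patches than the surrounding floor
  over <- unlist(sc$patches$cells)
  expect_lt(mean(sc$bathymetry$values[over]),
            mean(sc$bathymetry$values[-over]))
})

test_that("infeasible packing fails explicitly", {
  cfg <- tiny_config(n_patches = 400)
  expect_error(generate_seascape(cfg, max_tries = 30), "Infeasible packing")
})

test_that("surveys are deterministic given a seed and respect the design", {
  cfg <- tiny_config()
  sc <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(sc, buffers = 500))
  s1 <- simulate_communities(sc, met, cfg)
  s2 <- simulate_communities(sc, met, cfg)
  expect_identical(s1$fish, s2$fish)
  expect_identical(s1$benthic, s2$benthic)
  # point scores sum to the configured points per image
  cats <- c("coral", "macroalgae", "turf", "crustose_coralline", "sand")
  expect_true(all(rowSums(s1$benthic[cats]) == cfg$points_per_image))
  expect_true(all(s1$fish$fork_length_cm > 0))
  expect_true(all(s1$fish$cylinder %in% seq_len(cfg$n_cylinders_per_site)))
  # missing metric rows are named
  expect_error(simulate_communities(sc, met[-1, ], cfg), met$site_id[1])
})

test_that("estimated cover is a binomial draw around the true cover", {
  cfg <- tiny_config()
  sc <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(sc, buffers = 500))
  sv <- simulate_communities(sc, met, cfg)
  resp <- summarize_responses(sv, cfg$species)
  truth <- sv$truth[match(resp$site_id, sv$truth$site_id), ]
  n_pts <- cfg$n_images_per_site * cfg$points_per_image
  # 99% binomial envelope around each site's true cover
  se <- sqrt(truth$true_coral_cover * (1 - truth$true_coral_cover) / n_pts)
  z <- abs(resp$coral_cover_pct / 100 - truth$true_coral_cover) / se
  expect_true(all(z < qnorm(0.995) + 1))  # +1 z-unit of slack for small p
})

test_that("with all effects off, zone means are null and biomass ratios
           concentrate at 1 over replicate surveys", {
  cfg <- tiny_config(
    n_patches = 40, n_sites = 30,
    delta_fish = list(commercial = c(type1 = 0, type2 = 0),
                      noncommercial = c(type1 = 0, type2 = 0)),
    delta_coral_cover = c(type1 = 0, type2 = 0),
    delta_coral_richness = c(type1 = 0, type2 = 0),
    delta_macroalgae = c(type1 = 0, type2 = 0),
    beta_fish = c(distance_from_channel_km = 0, reef_area_500m_m2 = 0,
                  nearest_neighbor_m = 0),
    beta_coral = c(patch_size = 0, distance_from_channel_km = 0,
                   structural_complexity = 0))
  sc <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(sc, buffers = 500))
  diffs <- vapply(1:60, function(i) {
    sv <- simulate_communities(sc, met, cfg, seed = i)
    resp <- summarize_responses(sv, cfg$species)
    mean(log(resp$fish_total_biomass_g[resp$zone == "reserve"])) -
      mean(log(resp$fish_total_biomass_g[resp$zone == "control"]))
  }, 0)
  # Monte-Carlo CI around zero
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("a planted Type II fish effect yields the configured in/out ratio", {
  cfg <- tiny_config(
    n_patches = 40, n_sites = 36,
    delta_fish = list(commercial = c(type1 = 0, type2 = log(1.5)),
                      noncommercial = c(type1 = 0, type2 = log(1.5))),
    delta_coral_cover = c(type1 = 0, type2 = 0),
    delta_macroalgae = c(type1 = 0, type2 = 0),
    beta_fish = c(distance_from_channel_km = 0, reef_area_500m_m2 = 0,
                  nearest_neighbor_m = 0),
    sigma_site_fish = 0.1)
  sc <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(sc, buffers = 500))
  t2 <- sc$sites$type == "II"
  ratios <- vapply(1:200, function(i) {
    sv <- simulate_communities(sc, met, cfg, seed = 1000 + i)
    resp <- summarize_responses(sv, cfg$species)
    mean(resp$fish_total_biomass_g[t2 & resp$zone == "reserve"]) /
      mean(resp$fish_total_biomass_g[t2 & resp$zone == "control"])
  }, 0)
  expect_equal(mean(ratios), 1.5, tolerance = 0.08)
})
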