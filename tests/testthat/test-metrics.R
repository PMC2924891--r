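test_that("nearest neighbor handles lines, ties and matches the O(n^2) oracle", {
  expect_equal(nearest_neighbor(c(0, 3, 10), c(0, 0, 0)), c(3, 3, 7))
  expect_equal(nearest_neighbor(c(1, 1), c(2, 2)), c(0, 0))
  expect_warning(out <- nearest_neighbor(5, 5), "undefined")
  expect_true(is.na(out))
  withr::with_seed(99, {
    x <- runif(200, 0, 5000); y <- runif(200, 0, 5000)
  })
  expect_equal(nearest_neighbor(x, y), nn_oracle(x, y))
})

test_that("distance to features: hypotenuse, minimum rule, coincidence", {
  expect_equal(distance_to_feature(0, 0, rbind(c(3000, 4000))), 5)
  two <- rbind(c(2000, 0), c(9000, 0))
  expect_equal(distance_to_feature(0, 0, two), 2)
  expect_equal(distance_to_feature(700, -300, rbind(c(700, -300))), 0)
})

test_that("buffer reef area: lone patch, containment, monotonicity", {
  m <- matrix(1L, 60, 60)
  m[28:31, 28:31] <- 3L
  hab <- habitat_raster(m, 4)
  focal <- delineate_patches(hab)$cells[[1]]
  expect_equal(buffer_reef_area(focal, hab, c(200, 500, 1000))$reef_area_m2,
               c(0, 0, 0))

  # neighbor centred ~60 m away: fully inside a 100 m buffer, outside 40 m
  m2 <- m
  m2[28:31, 43:44] <- 3L
  hab2 <- habitat_raster(m2, 4)
  p <- delineate_patches(hab2)
  focal <- p$cells[[which.max(p$n_cells)]]
  ba <- buffer_reef_area(focal, hab2, c(40, 100))
  expect_equal(ba$reef_area_m2, c(0, 8 * 16))
})

test_that("buffer reef area equals the pixel-distance oracle on random scenes", {
  for (seed in 1:5) {
    hab <- random_habitat(50, 50, p_reef = 0.15, seed = seed + 7)
    p <- delineate_patches(hab)
    if (!nrow(p)) next
    take <- seq_len(min(4, nrow(p)))
    for (i in take) for (r in c(40, 120)) {
      got <- buffer_reef_area(p$cells[[i]], hab, r)$reef_area_m2
      expect_equal(got, buffer_oracle(p$cells[[i]], hab, r),
                   info = sprintf("seed %d patch %d radius %d", seed, i, r))
    }
    all3 <- vapply(p$cells[take], function(cc)
      buffer_reef_area(cc, hab, c(40, 120, 200))$reef_area_m2,
      numeric(3))
    expect_true(all(diff(all3) >= 0))  # monotone in radius
  }
})

test_that("bathymetric volume and surface: flat floor, prism, hemisphere", {
  m <- matrix(1L, 30, 30); m[10:19, 10:19] <- 3L
  hab <- habitat_raster(m, 4)
  cells <- delineate_patches(hab)$cells[[1]]

  flat <- bathymetry_grid(matrix(8, 30, 30), 4)
  out <- bathymetric_volume_and_surface(cells, flat)
  expect_equal(out$volume_m3, 0)
  expect_equal(out$surface_area_m2, length(cells) * 16)

  # cylinder: 10 cells rise 5 m above a 12 m floor
  cyl <- matrix(12, 30, 30)
  m2 <- matrix(1L, 30, 30); m2[15, 10:19] <- 3L
  cyl[15, 10:19] <- 7
  out2 <- bathymetric_volume_and_surface(delineate_patches(
    habitat_raster(m2, 4))$cells[[1]], bathymetry_grid(cyl, 4))
  expect_equal(out2$volume_m3, 10 * 16 * 5)

  # hemispherical bump on a fine grid: 3-D surface tends to 2 pi r^2
  r0 <- 25; h <- 0.25
  half <- ceiling((r0 + 4) / h); nn <- 2 * half + 1; ctr <- half + 1
  xy <- expand.grid(r = 1:nn, c = 1:nn)
  dx <- (xy$c - ctr) * h; dy <- (xy$r - ctr) * h
  rr2 <- dx^2 + dy^2
  depth <- matrix(30, nn, nn)
  inside <- rr2 < r0^2
  depth[cbind(xy$r, xy$c)[inside, ]] <- 30 - sqrt(pmax(r0^2 - rr2[inside], 0))
  mh <- matrix(1L, nn, nn)
  mh[cbind(xy$r, xy$c)[inside, ]] <- 3L
  cellsh <- delineate_patches(habitat_raster(mh, h))$cells[[1]]
  outh <- bathymetric_volume_and_surface(cellsh, bathymetry_grid(depth, h))
  expect_equal(outh$surface_area_m2, 2 * pi * r0^2, tolerance = 0.05)
})

test_that("coarse rugosity: flat, single-step hand value, reversal symmetry", {
  m <- matrix(1L, 10, 10); m[5, 3:6] <- 3L
  hab <- habitat_raster(m, 4)
  cells <- delineate_patches(hab)$cells[[1]]
  flat <- bathymetry_grid(matrix(6, 10, 10), 4)
  expect_equal(coarse_rugosity(cells, flat), 1)

  # two-cell chord with one 3 m step: (4 + 5) / 8 = 1.125
  m2 <- matrix(1L, 10, 10); m2[5, 4:5] <- 3L
  cells2 <- delineate_patches(habitat_raster(m2, 4))$cells[[1]]
  b <- matrix(6, 10, 10); b[5, 5] <- 3
  expect_equal(coarse_rugosity(cells2, bathymetry_grid(b, 4)), 1.125)

  # reversing the profile leaves the index unchanged
  b2 <- matrix(6, 10, 10); b2[5, 4] <- 3
  expect_equal(coarse_rugosity(cells2, bathymetry_grid(b2, 4)),
               coarse_rugosity(cells2, bathymetry_grid(b, 4)))

  expect_warning(one <- coarse_rugosity(cells2[1], flat), "single cell")
  expect_equal(one, 1)
})

test_that("fine rugosity is the mean contour/linear ratio and >= 1", {
  expect_equal(fine_rugosity(rep(10, 5), rep(10, 5)), 1)
  expect_equal(fine_rugosity(15, 10), 1.5)
  expect_error(fine_rugosity(9, 10), "shorter")
})

test_that("metric table units, invariants and scale covariance hold", {
  cfg <- tiny_config()
  sc <- generate_seascape(cfg)
  met <- suppressWarnings(seascape_metrics(sc, buffers = c(200, 500)))
  expect_equal(nrow(met), nrow(sc$sites))
  expect_true(all(met$nearest_neighbor_m >= 0))
  expect_true(all(met$area_hard_substrate_m2 <= met$area_m2))
  expect_true(all(met$reef_area_200m_m2 <= met$reef_area_500m_m2))
  expect_true(all(met$fine_rugosity >= 1 & met$coarse_rugosity >= 1))
  expect_named(attr(met, "units"), names(met))

  # same physical scene at doubled cell size: areas change within
  # discretization tolerance, never by a pixel-rescaling factor
  cfg2 <- tiny_config(cell_size_m = 8)
  sc2 <- generate_seascape(cfg2)
  met2 <- suppressWarnings(seascape_metrics(sc2, buffers = c(200, 500)))
  shared <- intersect(met$site_id, met2$site_id)
  a1 <- met$area_m2[match(shared, met$site_id)]
  a2 <- met2$area_m2[match(shared, met2$site_id)]
  expect_true(all(abs(a1 - a2) / pmax(a1, a2) < 0.8))
  expect_gt(cor(a1, a2), 0.95)
})
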