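#' Generate a synthetic lagoon seascape
#'
#' Places non-overlapping elliptical patch reefs on a sand/seagrass lagoon
#' floor, rasterizes them onto the habitat grid, builds a matching
#' bathymetry grid (floor sloping across the configured depth range, patch
#' tops rising to within 0.5-3 m of the surface), and assigns each patch a
#' latent seascape type by construction: Type II patches are seeded near
#' channel passes in dense arrays, drawn from the small end of the area
#' range and given high structural complexity; Type I patches sit in the
#' open lagoon, larger, more isolated and dome-shaped. A no-take reserve
#' polygon covers one sector of the lagoon, so zone membership is spatial
#' and partially confounded with the seascape gradient, as in real reserve
#' placements.
#'
#' @param config a [sim_config()].
#' @param max_tries rejection-sampling attempts per patch before declaring
#'   the packing infeasible.
#' @return A `seascape_scene`: habitat raster, bathymetry grid, `patches`
#'   tibble (true geometry, latent type, structural fields, rasterized cell
#'   sets, zone), reserve polygon, channel and mangrove coordinates, and the
#'   surveyed `sites` tibble.
#' @examples
#' sc <- generate_seascape(sim_config(n_patches = 12, n_sites = 8,
#'                                    lagoon_width_m = 600,
#'                                    lagoon_height_m = 600, rng_seed = 2))
#' nrow(sc$patches)
#' @export
generate_seascape <- function(config, max_tries = 500) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$rng_seed, "seascape", generate_seascape_impl(config, max_tries))
}

generate_seascape_impl <- function(config, max_tries) {
  W <- config$lagoon_width_m; H <- config$lagoon_height_m
  cs <- config$cell_size_m
  nc <- max(1L, round(W / cs)); nr <- max(1L, round(H / cs))

  patches <- place_patches(config, max_tries)
  hab <- matrix(1L, nr, nc)  # sand background

  # seagrass beds: inert background texture, never reef class
  n_sg <- max(3L, round(config$n_patches / 8))
  for (k in seq_len(n_sg)) {
    A <- exp(runif(1, log(500), log(5000)))
    q <- runif(1, 0.4, 0.9); a <- sqrt(A / (pi * q)); b <- q * a
    ctr <- c(runif(1, a, W - a), runif(1, a, H - a))
    th <- runif(1, 0, pi)
    ok <- TRUE
    if (nrow(patches)) {
      dd <- sqrt((patches$x - ctr[1])^2 + (patches$y - ctr[2])^2)
      ok <- all(dd > a + patches$semi_major + 2 * cs)
    }
    if (ok) {
      cells <- rasterize_ellipse(ctr[1], ctr[2], a, b, th, nr, nc, cs)
      hab[cells] <- 2L
    }
  }

  cell_list <- vector("list", nrow(patches))
  for (i in seq_len(nrow(patches))) {
    cells <- rasterize_ellipse(patches$x[i], patches$y[i],
                               patches$semi_major[i], patches$semi_minor[i],
                               patches$theta[i], nr, nc, cs)
    if (!length(cells)) {  # sub-cell patch: keep at least its centre cell
      rr <- min(nr, max(1L, nr - floor(patches$y[i] / cs)))
      cc <- min(nc, max(1L, ceiling(patches$x[i] / cs)))
      cells <- (cc - 1L) * nr + rr
    }
    hab[cells] <- 3L
    cell_list[[i]] <- cells
  }
  patches$cells <- cell_list
  patches$n_cells <- lengths(cell_list)

  bathy <- make_bathymetry(patches, nr, nc, cs, config)

  reserve_polygon <- sector_polygon(config$reserve_sector,
                                    config$reserve_fraction, W, H)
  if (nrow(patches)) {
    patches$zone <- ifelse(point_in_polygon(patches$x, patches$y,
                                            reserve_polygon),
                           "reserve", "control")
  } else patches$zone <- character(0)

  n_take <- min(config$n_sites, nrow(patches))
  idx <- if (n_take) sort(sample.int(nrow(patches), n_take)) else integer(0)
  sites <- tibble::tibble(
    site_id = sprintf("P%03d", patches$patch_id[idx]),
    patch_id = patches$patch_id[idx],
    zone = patches$zone[idx],
    type = patches$type[idx])

  structure(list(
    habitat = habitat_raster(hab, cs),
    bathymetry = bathymetry_grid(bathy, cs),
    patches = patches, sites = sites,
    reserve_polygon = reserve_polygon,
    channels = config$channel_coords, mangroves = config$mangrove_coords,
    width_m = W, height_m = H, config = config),
    class = "seascape_scene")
}

place_patches <- function(config, max_tries) {
  W <- config$lagoon_width_m; H <- config$lagoon_height_m
  cs <- config$cell_size_m
  n <- config$n_patches
  cols <- c("patch_id", "type", "x", "y", "area_m2", "semi_major",
            "semi_minor", "theta", "top_depth_m", "structural_complexity",
            "fine_rugosity_true", "sand_fraction")
  if (n == 0)
    return(tibble::tibble(patch_id = integer(0), type = character(0),
                          x = numeric(0), y = numeric(0), area_m2 = numeric(0),
                          semi_major = numeric(0), semi_minor = numeric(0),
                          theta = numeric(0), top_depth_m = numeric(0),
                          structural_complexity = integer(0),
                          fine_rugosity_true = numeric(0),
                          sand_fraction = numeric(0)))
  ch <- config$channel_coords
  # channels inside the reserve sector share weight = reserve_fraction so
  # Type II patches split across zones like the rest of the lagoon
  res_poly <- sector_polygon(config$reserve_sector, config$reserve_fraction,
                             W, H)
  eps <- 1e-3  # nudge rim points inward so boundary channels classify
  ch_in <- point_in_polygon(ch[, 1] + eps * (W / 2 - ch[, 1]),
                            ch[, 2] + eps * (H / 2 - ch[, 2]), res_poly)
  # weight channels so the Type II reserve share matches Type I's: Type I
  # occupies the lagoon outside the channel buffers, so its reserve share
  # is the reserve fraction of that admissible area (grid approximation)
  gx <- seq(W / 100, W, by = W / 50) - W / 100
  gy <- seq(H / 100, H, by = H / 50) - H / 100
  gpts <- expand.grid(x = gx, y = gy)
  dmin <- sapply(seq_len(nrow(ch)), function(j)
    sqrt((gpts$x - ch[j, 1])^2 + (gpts$y - ch[j, 2])^2))
  allowed <- row_mins(dmin) >= config$type1_channel_buffer_m
  in_res <- point_in_polygon(gpts$x, gpts$y, res_poly)
  p1_res <- if (any(allowed)) mean(in_res[allowed]) else config$reserve_fraction
  ch_w <- rep(1 / nrow(ch), nrow(ch))
  if (any(ch_in) && !all(ch_in)) {
    ch_w[ch_in] <- p1_res / sum(ch_in)
    ch_w[!ch_in] <- (1 - p1_res) / sum(!ch_in)
  }
  ann <- config$type2_channel_annulus_m
  # scale each channel's annulus area to its weight so that every Type II
  # cluster has the same patch density regardless of its zone share
  r_out <- sqrt(ann[1]^2 + ch_w * nrow(ch) * (ann[2]^2 - ann[1]^2))
  xs <- ys <- aa <- bb <- th <- ar <- numeric(n)
  # latent type and (for Type II) home channel are fixed per patch before
  # placement, so rejection sampling cannot bias the realized composition
  is_t2 <- runif(n) < config$p_type2
  type <- ifelse(is_t2, "II", "I")
  home <- sample.int(nrow(ch), n, replace = TRUE, prob = ch_w)
  for (i in seq_len(n)) {
    placed <- FALSE
    t2 <- is_t2[i]
    for (try in seq_len(max_tries)) {
      rng <- if (t2) config$type2_area_range_m2 else config$type1_area_range_m2
      A <- exp(runif(1, log(rng[1]), log(rng[2])))
      q <- runif(1, 0.45, 0.9)
      a <- sqrt(A / (pi * q)); b <- q * a
      if (t2) {
        rr <- sqrt(runif(1, ann[1]^2, r_out[home[i]]^2))
        phi <- runif(1, 0, 2 * pi)
        ctr <- ch[home[i], ] + rr * c(cos(phi), sin(phi))
      } else {
        ctr <- c(runif(1, 0, W), runif(1, 0, H))
      }
      ctr[1] <- min(max(ctr[1], a + 2 * cs), W - a - 2 * cs)
      ctr[2] <- min(max(ctr[2], a + 2 * cs), H - a - 2 * cs)
      dch <- min(sqrt((ch[, 1] - ctr[1])^2 + (ch[, 2] - ctr[2])^2))
      if (!t2 && dch < config$type1_channel_buffer_m) next
      if (t2 && (dch < ann[1] || dch > max(r_out))) next
      if (i > 1) {
        prev <- seq_len(i - 1)
        dd <- sqrt((xs[prev] - ctr[1])^2 + (ys[prev] - ctr[2])^2)
        if (any(dd <= a + aa[prev] + 2 * cs)) next
        # Type I patches keep a minimum isolation distance from each other
        if (!t2 && any(dd[!is_t2[prev]] < config$type1_min_spacing_m)) next
      }
      xs[i] <- ctr[1]; ys[i] <- ctr[2]; aa[i] <- a; bb[i] <- b
      th[i] <- runif(1, 0, pi); ar[i] <- A
      placed <- TRUE
      break
    }
    if (!placed)
      abort(sprintf(
        "Infeasible packing: could not place patch %d of %d after %d tries.",
        i, n, max_tries))
  }
  sc <- ifelse(type == "II",
               sample(1:3, n, TRUE, prob = c(0.10, 0.45, 0.45)),
               sample(0:2, n, TRUE, prob = c(0.35, 0.55, 0.10)))
  fr <- ifelse(type == "II",
               runif(n, config$fine_rugosity_range$type2[1],
                     config$fine_rugosity_range$type2[2]),
               runif(n, config$fine_rugosity_range$type1[1],
                     config$fine_rugosity_range$type1[2]))
  m <- config$sand_fraction_mean; v <- config$sand_fraction_sd^2
  k <- max(m * (1 - m) / v - 1, 0.5)
  tibble::tibble(
    patch_id = seq_len(n), type = type, x = xs, y = ys, area_m2 = ar,
    semi_major = aa, semi_minor = bb, theta = th,
    top_depth_m = runif(n, config$patch_top_depth_m[1],
                        config$patch_top_depth_m[2]),
    structural_complexity = as.integer(sc),
    fine_rugosity_true = fr,
    sand_fraction = stats::rbeta(n, m * k, (1 - m) * k))
}

# linear indices (column-major) of cells whose centres fall in the ellipse
rasterize_ellipse <- function(x0, y0, a, b, theta, nr, nc, cs) {
  c1 <- max(1L, floor((x0 - a) / cs)); c2 <- min(nc, ceiling((x0 + a) / cs) + 1L)
  r1 <- max(1L, nr - ceiling((y0 + a) / cs)); r2 <- min(nr, nr - floor((y0 - a) / cs) + 1L)
  if (c1 > c2 || r1 > r2) return(integer(0))
  rows <- r1:r2; colsv <- c1:c2
  xc <- (colsv - 0.5) * cs; yc <- (nr - rows + 0.5) * cs
  dx <- outer(rep(1, length(rows)), xc - x0)
  dy <- outer(yc - y0, rep(1, length(colsv)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ridx <- outer(rows, rep(1L, length(colsv)))
  cidx <- outer(rep(1L, length(rows)), colsv)
  (cidx[inside] - 1L) * nr + ridx[inside]
}

make_bathymetry <- function(patches, nr, nc, cs, config) {
  d1 <- config$depth_range_m[1]; d2 <- config$depth_range_m[2]
  W <- nc * cs; H <- nr * cs
  xc <- (seq_len(nc) - 0.5) * cs
  yc <- (nr - seq_len(nr) + 0.5) * cs
  floor_d <- outer(rep(1, nr), d1 + (d2 - d1) * xc / W) +
    0.35 * outer(sin(2 * pi * yc / H), rep(1, nc))
  floor_d <- pmin(pmax(floor_d, min(d1, d2) * 0.9), max(d1, d2) * 1.05)
  bathy <- floor_d
  for (i in seq_len(nrow(patches))) {
    cells <- patches$cells[[i]]
    if (!length(cells)) next
    rows <- ((cells - 1L) %% nr) + 1L
    colsv <- ((cells - 1L) %/% nr) + 1L
    px <- (colsv - 0.5) * cs; py <- (nr - rows + 0.5) * cs
    dx <- px - patches$x[i]; dy <- py - patches$y[i]
    thv <- patches$theta[i]
    u <- cos(thv) * dx + sin(thv) * dy
    v <- -sin(thv) * dx + cos(thv) * dy
    re <- pmin(sqrt((u / patches$semi_major[i])^2 +
                    (v / patches$semi_minor[i])^2), 1)
    top <- patches$top_depth_m[i]
    d <- top + (floor_d[cells] - top) * re^1.6
    if (patches$type[i] == "II")  # rough, complex relief
      d <- d + 0.7 * abs(sin(u / 5) * cos(v / 5))
    bathy[cells] <- pmin(pmax(d, 0.05), floor_d[cells])
  }
  bathy
}

sector_polygon <- function(sector, fraction, W, H) {
  switch(sector,
    west  = rbind(c(0, 0), c(fraction * W, 0), c(fraction * W, H), c(0, H)),
    east  = rbind(c((1 - fraction) * W, 0), c(W, 0), c(W, H), c((1 - fraction) * W, H)),
    south = rbind(c(0, 0), c(W, 0), c(W, fraction * H), c(0, fraction * H)),
    north = rbind(c(0, (1 - fraction) * H), c(W, (1 - fraction) * H), c(W, H), c(0, H)))
}

#' Point-in-polygon test (ray casting)
#'
#' @param x,y point coordinates (vectorized).
#' @param poly 2-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Polygon approximation of an ellipse
#' @param x,y centre; `a`,`b` semi-axes (m); `theta` rotation (rad);
#'   `n` vertices.
#' @return An `n` x 2 coordinate matrix.
#' @export
ellipse_polygon <- function(x, y, a, b, theta, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- a * cos(t); v <- b * sin(t)
  cbind(x + cos(theta) * u - sin(theta) * v,
        y + sin(theta) * u + cos(theta) * v)
}

#' @export
print.seascape_scene <- function(x, ...) {
  cat(sprintf("<seascape_scene> %g x %g m at %g m cells; %d patches (%d Type II), %d sites (%d reserve)\n",
              x$width_m, x$height_m, x$habitat$cell_size_m,
              nrow(x$patches), sum(x$patches$type == "II"),
              nrow(x$sites), sum(x$sites$zone == "reserve")))
  invisible(x)
}
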