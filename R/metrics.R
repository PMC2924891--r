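#' Nearest-neighbor distances among patch centroids
#'
#' @param x,y patch centroid coordinates (m), equal length >= 2 (a single
#'   patch yields `NA` with a warning: isolation is undefined).
#' @return Numeric vector: per patch, minimum centroid-to-centroid
#'   Euclidean distance to any other patch (m).
#' @examples
#' nearest_neighbor(c(0, 3, 10), c(0, 0, 0)) # 3 3 7
#' @export
nearest_neighbor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2) {
    warn("Nearest neighbor undefined with < 2 patches; returning NA.")
    return(rep(NA_real_, n))
  }
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Distance from a patch centroid to the nearest feature point
#'
#' @param x,y centroid coordinates (m), vectorized over patches.
#' @param feature_points 2-column (x, y) matrix of feature coordinates (m),
#'   e.g. channel openings or mangrove stands.
#' @return Distance in kilometres (minimum over feature points).
#' @examples
#' distance_to_feature(0, 0, rbind(c(3000, 4000))) # 5 km
#' @export
distance_to_feature <- function(x, y, feature_points) {
  feature_points <- as_coord_matrix(feature_points, "feature_points")
  vapply(seq_along(x), function(i)
    min(sqrt((feature_points[, 1] - x[i])^2 +
             (feature_points[, 2] - y[i])^2)), 0) / 1000
}

#' Reef area within a buffer around a focal patch
#'
#' Dilates the focal patch by `radius` (Euclidean distance transform of the
#' patch cell set) and sums the reef-class area whose cell centres fall in
#' the dilated footprint, excluding the focal patch's own cells by default.
#' Buffers reaching beyond the raster extent are computed on the available
#' extent and flagged.
#'
#' @param cells focal patch cell indices (column-major).
#' @param habitat a [habitat_raster()].
#' @param radius buffer radius in metres (one or more values).
#' @param include_self count the focal patch's own cells (default FALSE).
#' @return A tibble with `radius_m`, `reef_area_m2`, and `truncated`
#'   (TRUE when the buffer exceeds the raster extent).
#' @export
buffer_reef_area <- function(cells, habitat, radius = c(200, 500, 1000),
                             include_self = FALSE) {
  assert_positive(radius, "radius")
  mask <- habitat$values == reef_code(habitat)
  nr <- nrow(mask); nc <- ncol(mask)
  cs <- habitat$cell_size_m
  rows <- ((cells - 1L) %% nr) + 1L
  colsv <- ((cells - 1L) %/% nr) + 1L
  rmax <- max(radius)
  pad <- ceiling(rmax / cs) + 1L
  r1 <- max(1L, min(rows) - pad); r2 <- min(nr, max(rows) + pad)
  c1 <- max(1L, min(colsv) - pad); c2 <- min(nc, max(colsv) + pad)
  win <- mask[r1:r2, c1:c2, drop = FALSE]
  widx <- which(win)
  wr <- ((widx - 1L) %% nrow(win)) + r1
  wc <- ((widx - 1L) %/% nrow(win)) + c1
  gidx <- (wc - 1L) * nr + wr
  if (!include_self) {
    keep <- !(gidx %in% cells)
    wr <- wr[keep]; wc <- wc[keep]
  }
  dreef <- patch_boundary_distance(wr, wc, cells, rows, colsv, nr) * cs
  edge_gap <- min(rows - 1L, nr - rows, colsv - 1L, nc - colsv) * cs
  tibble::tibble(
    radius_m = radius,
    reef_area_m2 = vapply(radius, function(r) sum(dreef <= r) * cs^2, 0),
    truncated = radius > edge_gap)
}

# min distance (in cells, centre to centre) from query cells to a patch;
# only the patch's 8-neighbourhood boundary cells can be nearest to an
# external point, so the scan is restricted to them
patch_boundary_distance <- function(qr, qc, cells, rows, colsv, nr) {
  if (!length(qr)) return(numeric(0))
  nbr_off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  interior <- rows > 1L & rows < nr  # row-1/row-nr cells wrap columns: boundary
  for (off in nbr_off) interior <- interior & (cells + off) %in% cells
  br <- rows[!interior]; bc <- colsv[!interior]
  if (!length(br)) { br <- rows; bc <- colsv }
  d2 <- outer(qr, br, "-")^2 + outer(qc, bc, "-")^2
  sqrt(d2[cbind(seq_along(qr), max.col(-d2, ties.method = "first"))])
}

#' Bathymetric volume and 3-D surface area of a patch
#'
#' Volume is integrated against a local lagoon-floor reference depth, taken
#' as the maximum depth within a ring of `ring_cells` cells around the
#' patch (Chebyshev distance); each patch cell contributes
#' (reference - depth) x cell area, clamped at zero. Surface area sums
#' per-cell 3-D areas from central-difference slopes of the bathymetry.
#' Patches touching the raster edge get a truncated ring and are flagged.
#'
#' @param cells patch cell indices.
#' @param bathy a [bathymetry_grid()].
#' @param ring_cells ring width in cells for the floor reference (default 3).
#' @return One-row tibble: `volume_m3`, `surface_area_m2`,
#'   `floor_depth_m`, `edge_truncated`.
#' @export
bathymetric_volume_and_surface <- function(cells, bathy, ring_cells = 3) {
  depth <- bathy$values
  nr <- nrow(depth); nc <- ncol(depth)
  cs <- bathy$cell_size_m
  rows <- ((cells - 1L) %% nr) + 1L
  colsv <- ((cells - 1L) %/% nr) + 1L
  ring <- integer(0)
  for (dr in -ring_cells:ring_cells) for (dc in -ring_cells:ring_cells) {
    rr <- rows + dr; cc <- colsv + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ring <- c(ring, (cc[ok] - 1L) * nr + rr[ok])
  }
  ring <- setdiff(unique(ring), cells)
  truncated <- any(rows <= ring_cells | rows > nr - ring_cells |
                   colsv <= ring_cells | colsv > nc - ring_cells)
  floor_d <- if (length(ring)) max(depth[ring]) else max(depth[cells])
  vol <- sum(pmax(floor_d - depth[cells], 0)) * cs^2
  # central-difference slopes (one-sided at the raster edge)
  rp <- pmin(rows + 1L, nr); rm <- pmax(rows - 1L, 1L)
  cp <- pmin(colsv + 1L, nc); cm <- pmax(colsv - 1L, 1L)
  gy <- (depth[(colsv - 1L) * nr + rp] - depth[(colsv - 1L) * nr + rm]) /
    ((rp - rm) * cs)
  gx <- (depth[(cp - 1L) * nr + rows] - depth[(cm - 1L) * nr + rows]) /
    ((cp - cm) * cs)
  surf <- sum(sqrt(1 + gx^2 + gy^2)) * cs^2
  tibble::tibble(volume_m3 = vol, surface_area_m2 = surf,
                 floor_depth_m = floor_d, edge_truncated = truncated)
}

#' Coarse-scale rugosity from bathymetry along patch diameters
#'
#' Walks the maximum-length and maximum-width chords of the patch (its
#' principal axes through the centroid) in cell-size steps and accumulates
#' the over-terrain path length sqrt(cell^2 + d_depth^2) per step, divided
#' by the planar length; the index is the mean over the two chords and is
#' always >= 1 (1 = flat). Single-cell patches return 1 with a warning.
#'
#' @param cells patch cell indices.
#' @param bathy a [bathymetry_grid()].
#' @return Rugosity index (scalar).
#' @export
coarse_rugosity <- function(cells, bathy) {
  depth <- bathy$values
  nr <- nrow(depth)
  cs <- bathy$cell_size_m
  if (length(cells) < 2) {
    warn("Patch spans a single cell; coarse rugosity set to 1.")
    return(1)
  }
  rows <- ((cells - 1L) %% nr) + 1L
  colsv <- ((cells - 1L) %/% nr) + 1L
  xy <- cbind(colsv, rows)
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(cxy) / nrow(cxy), symmetric = TRUE)$vectors
  chord_index <- function(dir) {
    proj <- cxy %*% dir
    tmax <- max(proj); tmin <- min(proj)
    if (tmax - tmin < 1) return(NA_real_)
    tt <- seq(tmin, tmax, by = 1)
    pr <- round(ctr[2] + tt * dir[2]); pc <- round(ctr[1] + tt * dir[1])
    ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= ncol(depth)
    idx <- (pc[ok] - 1L) * nr + pr[ok]
    idx <- idx[idx %in% cells]
    idx <- idx[c(TRUE, diff(idx) != 0)]  # drop consecutive duplicates
    if (length(idx) < 2) return(NA_real_)
    dd <- c(0, diff(depth[idx]))
    sum(sqrt(cs^2 + dd^2)) / (length(idx) * cs)
  }
  r1 <- chord_index(ev[, 1]); r2 <- chord_index(ev[, 2])
  vals <- c(r1, r2)
  if (all(is.na(vals))) return(1)
  max(mean(vals, na.rm = TRUE), 1)
}

#' Fine-scale chain rugosity
#'
#' In-situ chain-and-tape rugosity: ratio of the draped chain (contour)
#' length to the straight-line transect length, averaged over replicate
#' transects.
#'
#' @param contour_length,linear_length replicate transect lengths (m);
#'   contour must be >= linear > 0.
#' @return Mean rugosity index, >= 1.
#' @examples
#' fine_rugosity(c(15, 12), c(10, 10)) # 1.35
#' @export
fine_rugosity <- function(contour_length, linear_length) {
  assert_positive(linear_length, "linear_length")
  if (any(contour_length < linear_length))
    abort("Contour length cannot be shorter than the linear length.")
  mean(contour_length / linear_length)
}

#' Compute the full seascape metric table for surveyed sites
#'
#' Builds the per-site table of configuration metrics (distance from
#' channel, distance to mangroves, nearest neighbor, reef area in 200/500 m
#' and 1 km buffers), composition metrics (area, hard-substrate area,
#' perimeter, edge:area ratio, estimated volume, bathymetric volume,
#' surface area) and patch-structure variables (fine and coarse rugosity,
#' structural complexity). Raster-derived metrics are computed on the
#' patches delineated from the habitat raster; sites are matched to the
#' delineated patch containing their survey coordinates. In-situ fields
#' (fine rugosity, structural complexity, sand fraction) come from the
#' survey data when given, else from the scene's generating truth.
#'
#' @param scene a `seascape_scene` (or a list with `habitat`, `bathymetry`,
#'   `sites` with x/y coordinates via `patch_id`, `channels`, `mangroves`).
#' @param survey optional `survey_data` from [simulate_communities()]
#'   supplying in-situ fields.
#' @param buffers buffer radii in metres.
#' @param include metric groups to compute: any of "configuration",
#'   "composition", "structure". Restricting groups skips expensive raster
#'   work that downstream steps do not need.
#' @param connectivity passed to [delineate_patches()].
#' @return A tibble, one row per site, with a `units` attribute naming the
#'   unit of every metric column.
#' @export
seascape_metrics <- function(scene, survey = NULL,
                             buffers = c(200, 500, 1000),
                             include = c("configuration", "composition",
                                         "structure"),
                             connectivity = 8) {
  include <- match.arg(include, c("configuration", "composition", "structure"),
                       several.ok = TRUE)
  hab <- scene$habitat; bat <- scene$bathymetry
  nr <- nrow(hab$values); cs <- hab$cell_size_m
  dl <- delineate_patches(hab, connectivity = connectivity)
  truth <- scene$patches
  sites <- scene$sites
  # match each surveyed site to the delineated patch containing its centre
  ctr_cell <- function(x, y) {
    r <- min(nr, max(1L, nr - floor(y / cs)))
    cc <- min(ncol(hab$values), max(1L, ceiling(x / cs)))
    (cc - 1L) * nr + r
  }
  t_idx <- match(sites$patch_id, truth$patch_id)
  d_idx <- vapply(t_idx, function(i) {
    cell <- ctr_cell(truth$x[i], truth$y[i])
    hit <- which(vapply(dl$cells, function(cc) cell %in% cc, TRUE))
    if (!length(hit)) {  # fall back to nearest delineated centroid
      hit <- which.min((dl$x - truth$x[i])^2 + (dl$y - truth$y[i])^2)
    }
    hit[1]
  }, 0L)

  out <- tibble::tibble(site_id = sites$site_id,
                        x = dl$x[d_idx], y = dl$y[d_idx])
  units <- c(site_id = "", x = "m", y = "m")

  insitu <- insitu_fields(sites, survey, truth[t_idx, ])

  if ("configuration" %in% include) {
    out$distance_from_channel_km <- distance_to_feature(out$x, out$y,
                                                        scene$channels)
    out$distance_to_mangroves_km <- distance_to_feature(out$x, out$y,
                                                        scene$mangroves)
    nn_all <- nearest_neighbor(dl$x, dl$y)
    out$nearest_neighbor_m <- nn_all[d_idx]
    for (r in sort(buffers, decreasing = TRUE)) {
      col <- buffer_col_name(r)
      out[[col]] <- vapply(d_idx, function(i)
        buffer_reef_area(dl$cells[[i]], hab, r)$reef_area_m2, 0)
      units[col] <- "m2"
    }
    units[c("distance_from_channel_km", "distance_to_mangroves_km",
            "nearest_neighbor_m")] <- c("km", "km", "m")
  }
  if ("composition" %in% include) {
    geo <- dplyr::bind_rows(lapply(d_idx, function(i)
      patch_geometry(dl$cells[[i]], nr, cs)))
    out$area_m2 <- geo$area_m2
    out$area_hard_substrate_m2 <- adjusted_hard_area(geo$area_m2,
                                                     insitu$sand_fraction)
    out$perimeter_m <- geo$perimeter_m
    out$edge_area_ratio <- geo$edge_area_ratio
    out$estimated_volume_m3 <- estimated_volume(geo$area_m2,
                                                insitu$fine_rugosity)
    bv <- dplyr::bind_rows(lapply(d_idx, function(i)
      bathymetric_volume_and_surface(dl$cells[[i]], bat)))
    out$bathymetric_volume_m3 <- bv$volume_m3
    out$surface_area_m2 <- bv$surface_area_m2
    units[c("area_m2", "area_hard_substrate_m2", "perimeter_m",
            "edge_area_ratio", "estimated_volume_m3",
            "bathymetric_volume_m3", "surface_area_m2")] <-
      c("m2", "m2", "m", "1/m", "m3", "m3", "m2")
  }
  if ("structure" %in% include) {
    out$fine_rugosity <- insitu$fine_rugosity
    out$coarse_rugosity <- vapply(d_idx, function(i)
      coarse_rugosity(dl$cells[[i]], bat), 0)
    out$structural_complexity <- insitu$structural_complexity
    units[c("fine_rugosity", "coarse_rugosity", "structural_complexity")] <-
      c("index", "index", "ordinal")
  }
  attr(out, "units") <- units[names(out)]
  out
}

buffer_col_name <- function(r) {
  if (r >= 1000 && r %% 1000 == 0) sprintf("reef_area_%dkm_m2", r %/% 1000)
  else sprintf("reef_area_%dm_m2", r)
}

insitu_fields <- function(sites, survey, truth_rows) {
  if (!is.null(survey)) {
    rug <- survey$rugosity |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(fine_rugosity = fine_rugosity(.data$contour_length_m,
                                                     .data$linear_length_m))
    ins <- dplyr::left_join(sites["site_id"], rug, by = "site_id") |>
      dplyr::left_join(survey$site_insitu, by = "site_id")
    list(fine_rugosity = ins$fine_rugosity,
         structural_complexity = ins$structural_complexity,
         sand_fraction = ins$sand_fraction)
  } else {
    list(fine_rugosity = truth_rows$fine_rugosity_true,
         structural_complexity = truth_rows$structural_complexity,
         sand_fraction = truth_rows$sand_fraction)
  }
}
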