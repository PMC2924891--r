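#' Delineate patch reefs from a habitat raster
#'
#' Merges reef-class cells into discrete patch reefs as connected
#' components of the class grid (8-connectivity by default, so diagonally
#' touching reef cells belong to one patch). Patch ids are stable: patches
#' are numbered by the row-major position of their first cell.
#'
#' @param habitat a [habitat_raster()].
#' @param connectivity 8 (default) or 4.
#' @param min_cells components smaller than this are dropped (default 1,
#'   i.e. keep everything).
#' @return A tibble with `patch_id`, `n_cells`, `area_m2`, centroid `x`,
#'   `y` (m), and a `cells` list-column of column-major linear indices.
#' @examples
#' m <- matrix(1L, 8, 8); m[2:4, 2:4] <- 3L
#' delineate_patches(habitat_raster(m, 4))
#' @export
delineate_patches <- function(habitat, connectivity = 8, min_cells = 1) {
  stopifnot(inherits(habitat, "habitat_raster"), connectivity %in% c(4, 8))
  mask <- habitat$values == reef_code(habitat)
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  if (!length(cells))
    return(tibble::tibble(patch_id = integer(0), n_cells = integer(0),
                          area_m2 = numeric(0), x = numeric(0), y = numeric(0),
                          cells = list()))
  edges <- lattice_edges(mask, connectivity)
  vid <- match(edges, cells)
  g <- igraph::make_graph(t(matrix(vid, ncol = 2)), n = length(cells),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  cs <- habitat$cell_size_m
  rows <- ((cells - 1L) %% nr) + 1L
  colsv <- ((cells - 1L) %/% nr) + 1L
  # stable ids: order components by row-major position of their first cell
  rm_pos <- (rows - 1L) * nc + colsv
  first_pos <- tapply(rm_pos, comp, min)
  relabel <- rank(first_pos)
  comp <- relabel[comp]
  keep <- as.integer(names(which(table(comp) >= min_cells)))
  out <- lapply(sort(keep), function(k) {
    sel <- comp == k
    list(cells = cells[sel],
         n = sum(sel),
         x = mean((colsv[sel] - 0.5) * cs),
         y = mean((nr - rows[sel] + 0.5) * cs))
  })
  tibble::tibble(
    patch_id = seq_along(out),
    n_cells = vapply(out, `[[`, 0L, "n"),
    area_m2 = vapply(out, `[[`, 0L, "n") * cs^2,
    x = vapply(out, `[[`, 0, "x"),
    y = vapply(out, `[[`, 0, "y"),
    cells = lapply(out, `[[`, "cells"))
}

# undirected adjacency edge list (pairs of linear indices) among TRUE cells
lattice_edges <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  e <- list()
  if (nc > 1) {
    both <- which(mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE])
    e$right <- cbind(both, both + nr)
  }
  if (nr > 1) {
    both <- which(mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE])
    r <- ((both - 1L) %% (nr - 1L)) + 1L; cc <- ((both - 1L) %/% (nr - 1L)) + 1L
    i <- (cc - 1L) * nr + r
    e$down <- cbind(i, i + 1L)
  }
  if (connectivity == 8 && nr > 1 && nc > 1) {
    both <- which(mask[-nr, -nc, drop = FALSE] & mask[-1, -1, drop = FALSE])
    r <- ((both - 1L) %% (nr - 1L)) + 1L; cc <- ((both - 1L) %/% (nr - 1L)) + 1L
    i <- (cc - 1L) * nr + r
    e$dr <- cbind(i, i + nr + 1L)
    both <- which(mask[-1, -nc, drop = FALSE] & mask[-nr, -1, drop = FALSE])
    r <- ((both - 1L) %% (nr - 1L)) + 1L; cc <- ((both - 1L) %/% (nr - 1L)) + 1L
    i <- (cc - 1L) * nr + r + 1L
    e$ur <- cbind(i, i + nr - 1L)
  }
  do.call(rbind, e)
}

#' Planimetric geometry of a patch reef
#'
#' Area is cell count times cell area; perimeter is measured on the
#' unsmoothed cell-edge boundary (number of exposed cell edges times the
#' cell size), which carries a known staircase bias relative to smoothed
#' digitized outlines. The edge:area ratio defaults to perimeter/area
#' (units 1/m) but accepts any function of (perimeter, area) since the
#' classical index is not uniquely defined.
#'
#' @param cells column-major linear cell indices of one patch.
#' @param nrow_grid number of raster rows.
#' @param cell_size_m cell size (m).
#' @param ratio_fn function(perimeter, area) for the edge:area column.
#' @return A one-row tibble: `area_m2`, `perimeter_m`, `edge_area_ratio`.
#' @examples
#' m <- matrix(FALSE, 10, 10)
#' m[3:7, 3:4] <- TRUE  # a 10 x 4 m block from 2 m cells
#' patch_geometry(which(m), nrow_grid = 10, cell_size_m = 2)
#' @export
patch_geometry <- function(cells, nrow_grid, cell_size_m,
                           ratio_fn = function(p, a) p / a) {
  if (!length(cells)) abort("Empty patch.")
  area <- length(cells) * cell_size_m^2
  per <- exposed_edges(cells, nrow_grid) * cell_size_m
  tibble::tibble(area_m2 = area, perimeter_m = per,
                 edge_area_ratio = ratio_fn(per, area))
}

exposed_edges <- function(cells, nr) {
  set <- cells
  rows <- ((set - 1L) %% nr) + 1L
  up    <- sum(rows == 1L) + sum(rows > 1L & !((set - 1L) %in% set))
  down  <- sum(rows == nr) + sum(rows < nr & !((set + 1L) %in% set))
  left  <- sum(!((set - nr) %in% set))
  right <- sum(!((set + nr) %in% set))
  up + down + left + right
}

#' Adjusted hard-substrate area
#'
#' Discounts patch area by the in-situ fraction of sand and seagrass on the
#' patch footprint, leaving the area of consolidated reef substrate.
#'
#' @param area_m2 patch area, m^2.
#' @param sand_seagrass_fraction fraction in `[0, 1]`.
#' @return Hard-substrate area, m^2.
#' @examples
#' adjusted_hard_area(1000, 0.25) # 750
#' @export
adjusted_hard_area <- function(area_m2, sand_seagrass_fraction) {
  assert_fraction(sand_seagrass_fraction, "sand_seagrass_fraction")
  if (any(area_m2 < 0)) abort("`area_m2` must be >= 0.")
  area_m2 * (1 - sand_seagrass_fraction)
}

#' Rugosity-scaled volume estimate
#'
#' Planimetric area times mean fine-scale rugosity: a first-order proxy for
#' the three-dimensional volume of reef structure.
#'
#' @param area_m2 patch area, m^2.
#' @param mean_fine_rugosity chain rugosity index, >= 1.
#' @return Estimated volume, m^3.
#' @export
estimated_volume <- function(area_m2, mean_fine_rugosity) {
  if (any(mean_fine_rugosity < 1)) abort("Rugosity index must be >= 1.")
  if (any(area_m2 < 0)) abort("`area_m2` must be >= 0.")
  area_m2 * mean_fine_rugosity
}

#' Trace the cell-edge boundary of a patch as polygon ring(s)
#'
#' Used for vector (GeoJSON) export of delineated patches. Rings follow the
#' exact unsmoothed cell-square outline; the longest ring is the exterior.
#'
#' @inheritParams patch_geometry
#' @return A list of ring coordinate matrices (closed: last vertex = first).
#' @export
patch_outline <- function(cells, nrow_grid, cell_size_m) {
  nr <- nrow_grid
  rows <- ((cells - 1L) %% nr) + 1L
  colsv <- ((cells - 1L) %/% nr) + 1L
  set <- cells
  segs <- list(); n <- 0
  x1 <- (colsv - 1L); x2 <- colsv           # in cell units
  yb <- (nr - rows); yt <- nr - rows + 1L
  add <- function(ax, ay, bx, by) {
    n <<- n + 1; segs[[n]] <<- c(ax, ay, bx, by)
  }
  for (i in seq_along(cells)) {
    c0 <- cells[i]; r <- rows[i]
    if (r == 1L || !((c0 - 1L) %in% set)) add(x2[i], yt[i], x1[i], yt[i])  # top, interior south
    if (r == nr || !((c0 + 1L) %in% set)) add(x1[i], yb[i], x2[i], yb[i])  # bottom
    if (!((c0 - nr) %in% set)) add(x1[i], yt[i], x1[i], yb[i])             # left
    if (!((c0 + nr) %in% set)) add(x2[i], yb[i], x2[i], yt[i])             # right
  }
  segm <- do.call(rbind, segs)
  key <- function(x, y) paste(x, y)
  starts <- key(segm[, 1], segm[, 2])
  used <- rep(FALSE, nrow(segm))
  by_start <- split(seq_len(nrow(segm)), starts)
  rings <- list()
  for (s in seq_len(nrow(segm))) {
    if (used[s]) next
    ring <- segm[s, 1:2]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nx <- segm[cur, 3:4]
      ring <- rbind(ring, nx)
      cand <- by_start[[key(nx[1], nx[2])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1) {
        # pinch vertex: prefer the leftmost turn to stay on this ring
        din <- segm[cur, 3:4] - segm[cur, 1:2]
        ang <- vapply(cand, function(j) {
          dout <- segm[j, 3:4] - segm[j, 1:2]
          atan2(din[1] * dout[2] - din[2] * dout[1],
                sum(din * dout))
        }, 0)
        cand <- cand[which.max(ang)]
      }
      cur <- cand[1]
    }
    rings[[length(rings) + 1]] <- ring * cell_size_m
  }
  rings[order(-vapply(rings, nrow, 0L))]
}
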