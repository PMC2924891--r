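#' Raster containers for habitat classes and bathymetry
#'
#' A habitat raster is an integer class grid on a square lattice in planar
#' metres; a bathymetry grid shares the same geometry and stores depth in
#' metres, positive down. Row 1 is the northernmost row; the origin is the
#' SW corner of the scene; cell registration is at pixel centres.
#'
#' @param values integer (habitat) or numeric (bathymetry) matrix.
#' @param cell_size_m side length of a (square) cell, metres.
#' @param class_map named integer vector mapping class names to codes; must
#'   cover every code present in the grid and include a `reef` class for
#'   patch delineation.
#' @return An object of class `habitat_raster` or `bathymetry_grid`.
#' @examples
#' hr <- habitat_raster(matrix(c(1, 3, 3, 1), 2, 2), cell_size_m = 4)
#' cell_centers(hr)
#' @export
habitat_raster <- function(values, cell_size_m,
                           class_map = c(sand = 1L, seagrass = 2L, reef = 3L)) {
  stopifnot(is.matrix(values))
  assert_positive(cell_size_m, "cell_size_m")
  codes <- unique(as.vector(values))
  missing <- setdiff(codes, unname(class_map))
  if (length(missing))
    abort(sprintf("Unmapped habitat codes: %s", paste(missing, collapse = ", ")))
  structure(
    list(values = matrix(as.integer(values), nrow(values), ncol(values)),
         cell_size_m = cell_size_m, class_map = class_map),
    class = "habitat_raster")
}

#' @rdname habitat_raster
#' @export
bathymetry_grid <- function(values, cell_size_m) {
  stopifnot(is.matrix(values))
  assert_positive(cell_size_m, "cell_size_m")
  if (any(values < 0)) abort("Depths must be >= 0 (positive down).")
  structure(list(values = values, cell_size_m = cell_size_m),
            class = "bathymetry_grid")
}

#' @rdname habitat_raster
#' @export
cell_centers <- function(values, cell_size_m = NULL) {
  if (inherits(values, c("habitat_raster", "bathymetry_grid"))) {
    cell_size_m <- values$cell_size_m
    values <- values$values
  }
  nr <- nrow(values); nc <- ncol(values)
  list(x = (seq_len(nc) - 0.5) * cell_size_m,
       y = (nr - seq_len(nr) + 0.5) * cell_size_m)  # row 1 = north
}

reef_code <- function(habitat) unname(habitat$class_map[["reef"]])

#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text raster IO (`.asc`): a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#'
#' @param x a `habitat_raster` or `bathymetry_grid`.
#' @param path file path.
#' @param digits significant digits written for numeric grids.
#' @return `read_ascii_grid()` returns a list with `values`, `cell_size_m`,
#'   and the lower-left corner; writers return `path` invisibly.
#' @export
write_ascii_grid <- function(x, path, digits = 6) {
  vals <- x$values
  hdr <- c(
    paste("ncols", ncol(vals)), paste("nrows", nrow(vals)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", format(x$cell_size_m, digits = 12)),
    "NODATA_value -9999")
  body <- apply(vals, 1, function(r) paste(format(r, digits = digits, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                 vapply(hdr, `[[`, "", 1))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(vals) == kv[["nrows"]], ncol(vals) == kv[["ncols"]])
  vals[vals == kv[["nodata_value"]]] <- NA_real_
  list(values = vals, cell_size_m = kv[["cellsize"]],
       xll = kv[["xllcorner"]], yll = kv[["yllcorner"]])
}
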