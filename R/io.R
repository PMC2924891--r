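#' Write scene vector features as GeoJSON
#'
#' Reserve boundary polygon, channel and mangrove points, and the true
#' patch polygons (elliptical outlines with latent type and zone as
#' properties), in planar projected coordinates (metres, origin at the
#' lagoon SW corner).
#'
#' @param scene a `seascape_scene`.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_scene_geojson <- function(scene, path) {
  close_ring <- function(m) rbind(m, m[1, , drop = FALSE])
  poly_feature <- function(coords, props) list(
    type = "Feature", properties = props,
    geometry = list(type = "Polygon",
                    coordinates = list(unname(apply(close_ring(coords), 1,
                                                    as.numeric,
                                                    simplify = FALSE)))))
  pt_feature <- function(xy, props) list(
    type = "Feature", properties = props,
    geometry = list(type = "Point", coordinates = as.numeric(xy)))
  feats <- list(poly_feature(scene$reserve_polygon, list(kind = "reserve")))
  for (i in seq_len(nrow(scene$channels)))
    feats[[length(feats) + 1]] <- pt_feature(scene$channels[i, ],
                                             list(kind = "channel", id = i))
  for (i in seq_len(nrow(scene$mangroves)))
    feats[[length(feats) + 1]] <- pt_feature(scene$mangroves[i, ],
                                             list(kind = "mangrove", id = i))
  p <- scene$patches
  for (i in seq_len(nrow(p))) {
    ring <- ellipse_polygon(p$x[i], p$y[i], p$semi_major[i], p$semi_minor[i],
                            p$theta[i])
    feats[[length(feats) + 1]] <- poly_feature(
      ring, list(kind = "patch", patch_id = p$patch_id[i],
                 type = p$type[i], zone = p$zone[i]))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON features written by [write_scene_geojson()]
#' @param path file path.
#' @return List with `reserve_polygon`, `channels`, `mangroves`, and a
#'   `patches` list of rings with properties.
#' @export
read_scene_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list(channels = NULL, mangroves = NULL, patches = list())
  for (f in gj$features) {
    kind <- f$properties$kind
    if (kind == "reserve") {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      out$reserve_polygon <- ring[-nrow(ring), , drop = FALSE]
    } else if (kind %in% c("channel", "mangrove")) {
      slot <- paste0(kind, "s")
      out[[slot]] <- rbind(out[[slot]], unlist(f$geometry$coordinates))
    } else if (kind == "patch") {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      out$patches[[length(out$patches) + 1]] <-
        list(ring = ring, properties = f$properties)
    }
  }
  for (slot in c("channels", "mangroves"))
    if (!is.null(out[[slot]])) colnames(out[[slot]]) <- c("x", "y")
  out
}

#' Metric-table CSV with a units header row
#'
#' The first data row below the header carries the unit of every column;
#' [read_metric_table()] strips it and restores numeric types and the
#' `units` attribute.
#'
#' @param metrics metric tibble (with `units` attribute, optional).
#' @param path file path.
#' @export
write_metric_table <- function(metrics, path) {
  units <- attr(metrics, "units") %||%
    setNames(rep("", ncol(metrics)), names(metrics))
  body <- dplyr::mutate(tibble::as_tibble(metrics),
                        dplyr::across(dplyr::everything(), as.character))
  out <- dplyr::bind_rows(tibble::as_tibble_row(units[names(metrics)]), body)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  units <- unlist(raw[1, ])
  body <- raw[-1, ]
  out <- tibble::as_tibble(lapply(body, function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (all(!is.na(num) | is.na(col))) num else col
  }))
  attr(out, "units") <- units
  out
}

#' Persist and restore survey data as tidy CSV files
#'
#' One file per observation table (`fish.csv`, `benthic.csv`,
#' `coral_species.csv`, `rugosity.csv`, `site_insitu.csv`, `sites.csv`)
#' plus `design.json` holding the survey design constants.
#'
#' @param survey a `survey_data`.
#' @param dir output directory (created if needed).
#' @export
write_survey_csv <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("fish", "benthic", "coral_species", "rugosity",
               "site_insitu", "sites", "truth"))
    readr::write_csv(survey[[nm]], file.path(dir, paste0(nm, ".csv")))
  jsonlite::write_json(survey$design, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(dir) {
  rd <- function(nm) readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                                     show_col_types = FALSE, progress = FALSE)
  structure(list(
    fish = rd("fish"), benthic = rd("benthic"),
    coral_species = rd("coral_species"), rugosity = rd("rugosity"),
    site_insitu = rd("site_insitu"), sites = rd("sites"),
    truth = rd("truth"),
    design = jsonlite::read_json(file.path(dir, "design.json"),
                                 simplifyVector = TRUE)),
    class = "survey_data")
}

effect_table_df <- function(tab) as.data.frame(tibble::as_tibble(tab))

#' Serialize an assessment report to JSON
#'
#' Versioned JSON schema carrying the pooled and stratified effect
#' tables, metric selections with AIC traces, collinear blocks, cluster
#' assignments, ANOSIM and species-screen results, and the seeds and
#' permutation counts of every stochastic step.
#'
#' @param report an `assessment_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  sel <- function(s) list(
    selected = s$selected, trace = as.data.frame(s$trace),
    pseudo_F = if (!is.null(s$fit)) s$fit$pseudo_F,
    p_value = if (!is.null(s$fit)) s$fit$p_value,
    prop_axis1 = if (!is.null(s$fit)) s$fit$prop_axis1,
    eigenvalues = if (!is.null(s$fit)) s$fit$eig,
    n_perm = if (!is.null(s$fit)) s$fit$n_perm,
    seed = if (!is.null(s$fit)) s$fit$seed)
  obj <- list(
    schema_version = "1.0",
    meta = report$meta,
    selection_fish = sel(report$selection_fish),
    selection_coral = sel(report$selection_coral),
    collinear_blocks = effect_table_df(report$collinear_blocks),
    clusters_fish = effect_table_df(report$clusters_fish),
    clusters_coral = effect_table_df(report$clusters_coral),
    pooled = effect_table_df(report$pooled),
    stratified_fish = effect_table_df(report$stratified_fish),
    stratified_coral = effect_table_df(report$stratified_coral),
    anosim = if (!is.null(report$anosim)) effect_table_df(report$anosim),
    species_screen = if (!is.null(report$species_screen))
      effect_table_df(report$species_screen))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Echo a simulation config to JSON and read it back
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_config_json <- function(config, path) {
  obj <- unclass(config)
  obj$species <- as.data.frame(obj$species)
  # named coefficient vectors serialize as objects so names survive
  for (nm in c("beta_fish", "beta_coral", "delta_coral_cover",
               "delta_coral_richness", "delta_macroalgae"))
    obj[[nm]] <- as.list(obj[[nm]])
  obj$delta_fish <- lapply(obj$delta_fish, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$species <- tibble::as_tibble(obj$species)
  obj$channel_coords <- matrix(obj$channel_coords, ncol = 2)
  obj$mangrove_coords <- matrix(obj$mangrove_coords, ncol = 2)
  obj$fine_rugosity_range <- lapply(obj$fine_rugosity_range, as.numeric)
  obj$delta_fish <- lapply(obj$delta_fish, unlist)
  for (nm in c("beta_fish", "beta_coral", "delta_coral_cover",
               "delta_coral_richness", "delta_macroalgae"))
    obj[[nm]] <- unlist(obj[[nm]])
  unknown <- setdiff(names(obj), names(formals(sim_config)))
  if (length(unknown))
    abort(paste("Unknown config keys:", paste(unknown, collapse = ", ")))
  do.call(sim_config, obj)
}
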