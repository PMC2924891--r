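#' Pipeline configuration
#'
#' Validated bundle of stage toggles and stage configurations for
#' [run_pipeline()]. Unknown keys are rejected.
#'
#' @param sim a [sim_config()].
#' @param stages named logical vector with entries `simulate`, `metrics`,
#'   `assess`; disabled stages are resumed from artifacts already present
#'   in the output directory.
#' @param n_perm permutations for CCA/ANOSIM tests.
#' @param k seascape groups per community.
#' @param buffers buffer radii (m) for the metric stage.
#' @param seed master seed (defaults to `sim$rng_seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c(simulate = TRUE, metrics = TRUE,
                                       assess = TRUE),
                            n_perm = 999, k = 2,
                            buffers = c(200, 500, 1000),
                            seed = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  known <- c("simulate", "metrics", "assess")
  if (!all(names(stages) %in% known) || !is.logical(stages))
    abort("`stages` must be a logical vector named simulate/metrics/assess.")
  full <- setNames(rep(TRUE, 3), known)
  full[names(stages)] <- stages
  structure(list(sim = sim, stages = full, n_perm = n_perm, k = k,
                 buffers = buffers, seed = seed %||% sim$rng_seed),
            class = "pipeline_config")
}

#' Run the simulate -> metrics -> assess pipeline
#'
#' Executes the enabled stages, persisting every intermediate artifact to
#' `out_dir` (ASCII-grid rasters, GeoJSON features, tidy CSV tables, JSON
#' report) so that later stages can resume from disk, and finishes by
#' writing a manifest with file checksums, seeds and package version.
#' Stage failures halt with the stage name; partial outputs are retained.
#'
#' @param config a [pipeline_config()] (a bare [sim_config()] is wrapped).
#' @param out_dir output directory.
#' @return The `assessment_report`, invisibly, with the manifest attached
#'   as attribute `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (inherits(config, "sim_config")) config <- pipeline_config(sim = config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    inform(sprintf("[pipeline] %s ...", name))
    tryCatch(code, error = function(e)
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e))
  }
  scene <- NULL; survey <- NULL
  if (config$stages[["simulate"]]) {
    sim_out <- stage("simulate", {
      scene <- generate_seascape(config$sim)
      true_met <- seascape_metrics(scene, buffers = config$buffers)
      survey <- simulate_communities(scene, true_met, config$sim,
                                     seed = config$seed)
      write_ascii_grid(scene$habitat, file.path(out_dir, "habitat.asc"))
      write_ascii_grid(scene$bathymetry, file.path(out_dir, "bathymetry.asc"))
      write_scene_geojson(scene, file.path(out_dir, "features.geojson"))
      write_config_json(config$sim, file.path(out_dir, "config.json"))
      write_survey_csv(survey, file.path(out_dir, "survey"))
      list(scene = scene, survey = survey)
    })
    scene <- sim_out$scene; survey <- sim_out$survey
  }
  if (config$stages[["metrics"]]) {
    stage("metrics", {
      if (is.null(scene)) abort("metrics stage needs the simulate stage or ingested rasters")
      met <- seascape_metrics(scene, survey = survey, buffers = config$buffers)
      write_metric_table(met, file.path(out_dir, "metrics.csv"))
      responses <- summarize_responses(survey, config$sim$species)
      readr::write_csv(responses, file.path(out_dir, "responses.csv"))
      readr::write_csv(species_biomass_matrix(survey, config$sim$species),
                       file.path(out_dir, "species_biomass.csv"))
    })
  }
  report <- stage("assess", {
    met <- read_metric_table(file.path(out_dir, "metrics.csv"))
    responses <- readr::read_csv(file.path(out_dir, "responses.csv"),
                                 show_col_types = FALSE, progress = FALSE)
    biomass <- readr::read_csv(file.path(out_dir, "species_biomass.csv"),
                               show_col_types = FALSE, progress = FALSE)
    if (!config$stages[["assess"]]) return(NULL)
    rep <- assess_reserve(met, responses, species_biomass = biomass,
                          k = config$k, n_perm = config$n_perm,
                          seed = config$seed)
    write_report_json(rep, file.path(out_dir, "report.json"))
    rep
  })
  manifest <- pipeline_manifest(out_dir, config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(report, "manifest") <- manifest
  invisible(report)
}

pipeline_manifest <- function(out_dir, config) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  list(
    package = "seascapeCI",
    version = as.character(utils::packageVersion("seascapeCI")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, n_perm = config$n_perm,
    created = "run_pipeline",
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
}
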