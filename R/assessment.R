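response_columns <- function() {
  c("fish_richness", "fish_total_biomass_g", "fish_commercial_biomass_g",
    "coral_richness", "coral_cover_pct", "coral_macroalgal_ratio")
}

size_metric_columns <- function() {
  c("area_m2", "area_hard_substrate_m2", "perimeter_m", "edge_area_ratio",
    "estimated_volume_m3", "bathymetric_volume_m3")
}

fish_metric_columns <- function() {
  c("distance_from_channel_km", "reef_area_500m_m2", "nearest_neighbor_m")
}

#' Assemble per-site records for the Control-Impact contrasts
#'
#' Joins the community response table with the fish and coral seascape
#' group assignments, producing the analysis table the pooled and
#' stratified contrasts run on.
#'
#' @param responses tibble from [summarize_responses()].
#' @param fish_groups,coral_groups `cluster_assignment` tibbles (or any
#'   tibble with `site_id` and `group`).
#' @return Tibble with `site_id`, `zone`, `fish_group`, `coral_group` and
#'   the six response columns.
#' @export
site_records <- function(responses, fish_groups, coral_groups) {
  out <- responses |>
    dplyr::left_join(dplyr::rename(tibble::as_tibble(fish_groups),
                                   fish_group = "group"), by = "site_id") |>
    dplyr::left_join(dplyr::rename(tibble::as_tibble(coral_groups),
                                   coral_group = "group"), by = "site_id")
  miss <- is.na(out$fish_group) | is.na(out$coral_group)
  if (any(miss))
    abort(paste("Sites missing a group assignment:",
                paste(out$site_id[miss], collapse = ", ")))
  out
}

#' Normalizing transforms used for the Control-Impact ANOVAs
#'
#' Biomass, richness and ratio responses are tested on the log10 scale
#' (with a +1 offset guarding empty sites) and percent cover on the
#' arcsine-square-root scale, the standard variance-stabilizing choices
#' for these data; percent effect sizes are always computed from the raw
#' zone means.
#' @return Named character vector response -> transform.
#' @export
default_response_test_transforms <- function() {
  c(fish_richness = "log10", fish_total_biomass_g = "log10",
    fish_commercial_biomass_g = "log10", coral_richness = "log10",
    coral_cover_pct = "arcsine_sqrt_pct", coral_macroalgal_ratio = "log10")
}

apply_test_transform <- function(vals, method) {
  switch(method %||% "none",
         log10 = log10(vals + 1),
         arcsine_sqrt_pct = asin(sqrt(pmin(pmax(vals / 100, 0), 1))),
         vals)
}

effect_row <- function(vals, zone, response, stratum,
                       test_transform = "none") {
  zin <- zone == "reserve"
  base <- tibble::tibble(
    response = response, stratum = stratum,
    n_in = sum(zin), n_out = sum(!zin),
    mean_in = mean(vals[zin]), mean_out = mean(vals[!zin]))
  if (base$n_in < 2 || base$n_out < 2) {
    return(dplyr::mutate(base, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                         p_value = NA_real_, pct_diff_outside = NA_real_,
                         pct_diff_inside = NA_real_,
                         direction = NA_character_, tested = FALSE,
                         note = "insufficient sites in a zone"))
  }
  av <- one_way_anova(apply_test_transform(vals, test_transform),
                      factor(ifelse(zin, "reserve", "control"),
                             levels = c("control", "reserve")))
  pct_out <- if (base$mean_out > 0)
    proportional_difference(base$mean_in, base$mean_out, "outside") else NA_real_
  pct_in <- if (base$mean_in > 0)
    proportional_difference(base$mean_in, base$mean_out, "inside") else NA_real_
  dplyr::mutate(base, F = av$F, df1 = av$df1, df2 = av$df2,
                p_value = av$p_value,
                pct_diff_outside = pct_out, pct_diff_inside = pct_in,
                direction = dplyr::case_when(
                  base$mean_in > base$mean_out ~ "inside_higher",
                  base$mean_in < base$mean_out ~ "outside_higher",
                  TRUE ~ "equal"),
                tested = TRUE, note = NA_character_)
}

#' Pooled Control-Impact contrasts
#'
#' The traditional reserve assessment: one-way ANOVA of each response
#' between reserve and control over all sites, ignoring seascape
#' structure. Effect sizes are reported under both percent-difference
#' conventions (outside baseline and inside baseline).
#'
#' @param sites site-record tibble (needs `zone` plus response columns).
#' @param responses response columns to test (defaults to the six
#'   standard community responses present).
#' @return An `effect_table` tibble, one row per response.
#' @export
pooled_ci <- function(sites, responses = NULL,
                      test_transforms = default_response_test_transforms()) {
  responses <- responses %||% intersect(response_columns(), names(sites))
  if (!all(c("reserve", "control") %in% sites$zone))
    abort("Both zones must be represented.")
  out <- dplyr::bind_rows(lapply(responses, function(rv)
    effect_row(sites[[rv]], sites$zone, rv, "pooled",
               test_transform = test_transforms[rv])))
  structure(out, class = c("effect_table", class(out)))
}

#' Seascape-stratified Control-Impact contrasts
#'
#' Reserve effects tested only among sites sharing a seascape group:
#' separate one-way ANOVAs within each group of the chosen community
#' classification. Strata where a zone has fewer than two sites are
#' reported as explicit untested gap rows rather than dropped.
#'
#' @inheritParams pooled_ci
#' @param grouping "fish" or "coral" (uses `fish_group` / `coral_group`),
#'   or the name of any factor column in `sites`.
#' @return An `effect_table` tibble, one row per response x stratum.
#' @export
stratified_ci <- function(sites, grouping = c("fish", "coral"),
                          responses = NULL,
                          test_transforms = default_response_test_transforms()) {
  if (length(grouping) == 1 && grouping %in% names(sites)) gcol <- grouping
  else gcol <- paste0(match.arg(grouping), "_group")
  responses <- responses %||% intersect(response_columns(), names(sites))
  g <- droplevels(as.factor(sites[[gcol]]))
  out <- dplyr::bind_rows(lapply(levels(g), function(lv) {
    sel <- g == lv
    dplyr::bind_rows(lapply(responses, function(rv)
      effect_row(sites[[rv]][sel], sites$zone[sel], rv,
                 paste0("Type ", lv),
                 test_transform = test_transforms[rv])))
  }))
  structure(out, class = c("effect_table", class(out)))
}

#' Species-level reserve response screen
#'
#' Within each seascape group, tests every sufficiently prevalent species
#' for a reserve/control biomass difference by one-way ANOVA at
#' `alpha` (uncorrected by default, matching common assessment practice;
#' a Benjamini-Hochberg option is available). Species absent from one
#' zone within a group are flagged untestable, never significant.
#'
#' @param biomass site x species biomass tibble
#'   (from [species_biomass_matrix()]).
#' @param groups factor of seascape groups per site.
#' @param zone zone per site ("reserve"/"control").
#' @param min_prevalence minimum fraction of the group's sites where the
#'   species occurs (default 0.2).
#' @param alpha significance level (default 0.05).
#' @param p_adjust "none" (default) or any [stats::p.adjust()] method.
#' @return Tibble: species x group with `F`, `p_value`, `direction`,
#'   `prevalence`, `testable`, `significant`.
#' @export
species_response_screen <- function(biomass, groups, zone,
                                    min_prevalence = 0.2, alpha = 0.05,
                                    p_adjust = "none") {
  m <- as.matrix(biomass[setdiff(names(biomass), "site_id")])
  groups <- droplevels(as.factor(groups))
  zin <- zone == "reserve"
  rows <- list()
  for (lv in levels(groups)) {
    sel <- groups == lv
    for (sp in colnames(m)) {
      v <- m[sel, sp]
      prev <- mean(v > 0)
      in_ok <- any(v[zin[sel]] > 0); out_ok <- any(v[!zin[sel]] > 0)
      testable <- prev >= min_prevalence && in_ok && out_ok &&
        sum(zin[sel]) >= 2 && sum(!zin[sel]) >= 2
      if (testable) {
        av <- one_way_anova(v, factor(ifelse(zin[sel], "reserve", "control"),
                                      levels = c("control", "reserve")))
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = sp, group = lv, prevalence = prev, testable = TRUE,
          F = av$F, p_value = av$p_value,
          direction = if (av$mean_reserve > av$mean_control)
            "inside_higher" else "outside_higher")
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = sp, group = lv, prevalence = prev, testable = FALSE,
          F = NA_real_, p_value = NA_real_, direction = NA_character_)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- out$p_value
  for (lv in levels(groups)) {
    sel <- out$group == lv & out$testable
    out$p_adjusted[sel] <- stats::p.adjust(out$p_value[sel], method = p_adjust)
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}

#' Run the full seascape-stratified reserve assessment
#'
#' The complete analysis chain on surveyed data: transform and standardize
#' the metric table, screen collinearity and collapse blocks to PC1,
#' select metrics for the fish and coral communities by AIC forward
#' selection under CCA with permutation tests, cluster sites into
#' seascape groups on each community's selected metrics, then contrast
#' reserve and control pooled and within groups, run the two-way crossed
#' ANOSIM on Bray-Curtis fish dissimilarities, and screen species-level
#' responses.
#'
#' @param metrics metric table from [seascape_metrics()].
#' @param responses community responses from [summarize_responses()].
#' @param species_biomass optional site x species biomass for ANOSIM and
#'   the species screen.
#' @param k number of seascape groups per community (default 2).
#' @param n_perm permutations for CCA and ANOSIM tests.
#' @param seed integer seed governing every permutation stream.
#' @param r_threshold collinearity screen threshold (default 0.2).
#' @param alpha significance level for reporting.
#' @return An `assessment_report` (list) with elements `selection_fish`,
#'   `selection_coral`, `collinear_blocks`, `clusters_fish`,
#'   `clusters_coral`, `pooled`, `stratified_fish`, `stratified_coral`,
#'   `anosim`, `species_screen`, `sites`, and `meta`.
#' @export
assess_reserve <- function(metrics, responses, species_biomass = NULL,
                           k = 2, n_perm = 999, seed = 1L,
                           r_threshold = 0.2, alpha = 0.05) {
  env <- build_env_matrix(metrics)
  coll <- collapse_collinear(env, threshold = r_threshold,
                             names_for = list(patch_size = size_metric_columns()))
  fish_Y <- responses[c("site_id", "fish_richness", "fish_total_biomass_g",
                        "fish_commercial_biomass_g")]
  coral_Y <- responses[c("site_id", "coral_richness", "coral_cover_pct",
                         "coral_macroalgal_ratio")]
  stopifnot(identical(env$site_id, responses$site_id))
  sel_fish <- aic_forward_select(fish_Y, coll$env, n_perm = n_perm,
                                 seed = child_seed(seed, "sel_fish"))
  sel_coral <- aic_forward_select(coral_Y, coll$env, n_perm = n_perm,
                                  seed = child_seed(seed, "sel_coral"))
  cluster_cols <- function(sel) {
    if (length(sel$selected)) sel$selected
    else setdiff(names(coll$env), "site_id")
  }
  cl_fish <- cluster_sites(coll$env, cluster_cols(sel_fish), k = k)
  cl_coral <- cluster_sites(coll$env, cluster_cols(sel_coral), k = k)
  sites <- site_records(responses, cl_fish, cl_coral)
  pooled <- pooled_ci(sites)
  strat_fish <- stratified_ci(sites, "fish",
                              responses = c("fish_richness",
                                            "fish_total_biomass_g",
                                            "fish_commercial_biomass_g"))
  strat_coral <- stratified_ci(sites, "coral",
                               responses = c("coral_richness",
                                             "coral_cover_pct",
                                             "coral_macroalgal_ratio"))
  anos <- NULL; screen <- NULL
  if (!is.null(species_biomass)) {
    D <- bray_curtis(species_biomass)
    # crossed zone x seascape-group ANOSIM; an incomplete design (a group
    # with a single zone) degrades to the one-way zone test with a note
    anos <- tryCatch(
      anosim(D, grouping = factor(sites$zone), block = sites$fish_group,
             n_perm = n_perm, seed = child_seed(seed, "anosim")),
      error = function(e) {
        out <- anosim(D, grouping = factor(sites$zone), n_perm = n_perm,
                      seed = child_seed(seed, "anosim"))
        attr(out, "note") <- conditionMessage(e)
        out
      })
    screen <- species_response_screen(species_biomass, sites$fish_group,
                                      sites$zone, alpha = alpha)
  }
  structure(list(
    selection_fish = sel_fish, selection_coral = sel_coral,
    collinear_blocks = coll$blocks,
    clusters_fish = cl_fish, clusters_coral = cl_coral,
    pooled = pooled, stratified_fish = strat_fish,
    stratified_coral = strat_coral,
    anosim = anos, species_screen = screen, sites = sites,
    meta = list(k = k, n_perm = n_perm, seed = seed, alpha = alpha,
                r_threshold = r_threshold, n_sites = nrow(sites))),
    class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %d sites | fish metrics: %s | coral metrics: %s\n",
              x$meta$n_sites,
              paste(x$selection_fish$selected, collapse = "+"),
              paste(x$selection_coral$selected, collapse = "+")))
  sig <- function(tab) sum(tab$tested & tab$p_value < x$meta$alpha, na.rm = TRUE)
  cat(sprintf("  significant contrasts: pooled %d, stratified fish %d, stratified coral %d (alpha = %.2f)\n",
              sig(x$pooled), sig(x$stratified_fish), sig(x$stratified_coral),
              x$meta$alpha))
  invisible(x)
}
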