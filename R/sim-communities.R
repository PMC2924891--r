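#' Simulate fish and benthic surveys over a seascape
#'
#' Observation model for the survey protocol. Fish counts per species per
#' cylinder are Poisson with a log link on standardized seascape covariates
#' (distance from channel, reef area in the 500 m buffer, nearest-neighbor
#' distance; buffer area and isolation enter on the log10 scale), a
#' lognormal site effect, and a reserve effect applied only inside the
#' reserve and only for the configured latent type(s). Fork lengths are
#' lognormal per species and convert to biomass allometrically. True coral
#' and macroalgal covers are logit-normal with covariates (patch size =
#' log area, distance from channel, structural complexity) and their own
#' planted reserve effects; benthic point-intercept scores are multinomial
#' draws of `points_per_image` points over coral / macroalgae / turf /
#' crustose-coralline / sand on `n_images_per_site` images. Chain-rugosity
#' replicates and the ordinal structural-complexity score are observed with
#' small measurement noise around the scene's truth.
#'
#' @param scene a `seascape_scene`.
#' @param true_metrics metric table from [seascape_metrics()] for the
#'   scene's sites (must cover every surveyed site; missing sites are an
#'   error and are named).
#' @param config the [sim_config()] used to build the scene.
#' @param seed RNG seed for the survey draws; defaults to a child of
#'   `config$rng_seed` so repeated calls are reproducible.
#' @return A `survey_data` list of tidy tibbles: `fish` (one row per
#'   individual: site, cylinder, species, count, fork length), `benthic`
#'   (per image category counts), `coral_species` (presence list),
#'   `rugosity` (chain replicates), `site_insitu`, `sites`, and the
#'   simulation `truth` (true covers and expected fish intensity).
#' @export
simulate_communities <- function(scene, true_metrics, config,
                                 seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  sites <- scene$sites
  missing <- setdiff(sites$site_id, true_metrics$site_id)
  if (length(missing))
    abort(paste("Metric table lacks sites:", paste(missing, collapse = ", ")))
  with_stage_seed(seed, "communities",
                  simulate_communities_impl(scene, true_metrics, config))
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

simulate_communities_impl <- function(scene, met, config) {
  sites <- scene$sites
  met <- met[match(sites$site_id, met$site_id), ]
  n <- nrow(sites)
  sp <- config$species
  n_sp <- nrow(sp)
  in_res <- sites$zone == "reserve"
  t2 <- sites$type == "II"

  z_fish <- cbind(
    distance_from_channel_km = zscore(met$distance_from_channel_km),
    reef_area_500m_m2 = zscore(log10(pmax(met$reef_area_500m_m2, 1))),
    nearest_neighbor_m = zscore(log10(pmax(met$nearest_neighbor_m, 1))))
  eta_site <- drop(z_fish %*% config$beta_fish[colnames(z_fish)]) +
    rnorm(n, 0, config$sigma_site_fish)
  delta_site <- function(d) ifelse(in_res, ifelse(t2, d["type2"], d["type1"]), 0)
  d_comm <- delta_site(config$delta_fish$commercial)
  d_nonc <- delta_site(config$delta_fish$noncommercial)

  fish <- vector("list", n)
  n_cyl <- config$n_cylinders_per_site
  for (i in seq_len(n)) {
    lam <- exp(sp$log_abundance + eta_site[i] +
                 ifelse(sp$commercial, d_comm[i], d_nonc[i]))
    counts <- matrix(rpois(n_sp * n_cyl, rep(lam, n_cyl)), n_sp, n_cyl)
    tot <- sum(counts)
    if (tot == 0) { fish[[i]] <- NULL; next }
    idx <- which(counts > 0, arr.ind = TRUE)
    reps <- counts[idx]
    srow <- rep(idx[, 1], reps); cyl <- rep(idx[, 2], reps)
    fish[[i]] <- tibble::tibble(
      site_id = sites$site_id[i], cylinder = cyl,
      species = sp$species[srow], count = 1L,
      fork_length_cm = rlnorm(length(srow), sp$meanlog_length[srow],
                              config$sigma_length))
  }
  fish <- dplyr::bind_rows(fish)

  # benthic truth on the logit scale
  z_cor <- cbind(
    patch_size = zscore(log10(pmax(met$area_m2, 1))),
    distance_from_channel_km = zscore(met$distance_from_channel_km),
    structural_complexity = zscore(met$structural_complexity))
  qlogis_ <- stats::qlogis; plogis_ <- stats::plogis
  eta_cov <- drop(z_cor %*% config$beta_coral[colnames(z_cor)])
  d_cov <- delta_site(config$delta_coral_cover)
  d_alg <- delta_site(config$delta_macroalgae)
  d_ric <- delta_site(config$delta_coral_richness)
  true_coral <- plogis_(qlogis_(config$coral_cover_baseline) + eta_cov +
                          d_cov + rnorm(n, 0, config$sigma_coral))
  true_algae <- plogis_(qlogis_(config$macroalgae_baseline) - 0.3 * eta_cov +
                          d_alg + rnorm(n, 0, config$sigma_coral))
  true_turf <- plogis_(qlogis_(config$turf_baseline) + rnorm(n, 0, 0.2))
  true_cca <- plogis_(qlogis_(config$cca_baseline) + rnorm(n, 0, 0.2))
  p <- cbind(coral = true_coral, macroalgae = true_algae, turf = true_turf,
             crustose_coralline = true_cca)
  over <- rowSums(p) > 0.92
  p[over, ] <- p[over, ] * 0.92 / rowSums(p)[over]
  p <- cbind(p, sand = 1 - rowSums(p))

  n_img <- config$n_images_per_site; pts <- config$points_per_image
  benthic <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    m <- t(rmultinom(n_img, pts, p[i, ]))
    colnames(m) <- colnames(p)
    dplyr::bind_cols(tibble::tibble(site_id = sites$site_id[i],
                                    image = seq_len(n_img)),
                     tibble::as_tibble(m))
  }))

  rich <- rpois(n, exp(log(config$coral_richness_mean) + 0.25 * eta_cov + d_ric))
  coral_species <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    k <- min(rich[i], 40)
    if (k == 0) return(NULL)
    tibble::tibble(site_id = sites$site_id[i],
                   species = sprintf("coral%02d", sample.int(40, k)))
  }))

  truth <- scene$patches[match(sites$patch_id, scene$patches$patch_id), ]
  n_rug <- config$n_fine_rugosity_reps
  rugosity <- tibble::tibble(
    site_id = rep(sites$site_id, each = n_rug),
    replicate = rep(seq_len(n_rug), n),
    linear_length_m = 10,
    contour_length_m = pmax(10, 10 * (rep(truth$fine_rugosity_true, each = n_rug) +
                                        rnorm(n * n_rug, 0, 0.05))))
  site_insitu <- tibble::tibble(
    site_id = sites$site_id,
    structural_complexity = truth$structural_complexity,
    sand_fraction = pmin(pmax(truth$sand_fraction +
                                rnorm(n, 0, 0.02), 0), 1))

  structure(list(
    fish = fish, benthic = benthic, coral_species = coral_species,
    rugosity = rugosity, site_insitu = site_insitu,
    sites = sites,
    truth = tibble::tibble(site_id = sites$site_id,
                           true_coral_cover = true_coral,
                           true_macroalgae = true_algae,
                           eta_fish = eta_site),
    design = list(n_cylinders = n_cyl, n_images = n_img,
                  points_per_image = pts)),
    class = "survey_data")
}

#' Summarize surveys into per-site community response variables
#'
#' Applies the standard response definitions: fish species richness (species
#' seen in any cylinder), total and commercial biomass (allometric mass
#' summed per cylinder per species, then averaged over all cylinders,
#' including empty ones), stony-coral species richness, percent coral
#' cover (mean over images of scored coral points / points per image), and
#' the coral:macroalgal cover ratio (turf and crustose coralline excluded
#' by construction; 0.5-point pseudocounts guard empty categories).
#'
#' @param survey a `survey_data`.
#' @param species species table with `species`, `commercial`, `a`, `b`.
#' @return A tibble, one row per site, with `zone` and latent `type`
#'   carried through.
#' @export
summarize_responses <- function(survey, species) {
  species <- tibble::as_tibble(species)
  n_cyl <- survey$design$n_cylinders
  pts <- survey$design$points_per_image
  sites <- survey$sites

  fish <- survey$fish |>
    dplyr::left_join(species[, c("species", "commercial", "a", "b")],
                     by = "species") |>
    dplyr::mutate(biomass_g = allometric_biomass(.data$fork_length_cm,
                                                 .data$a, .data$b) * .data$count)
  by_site <- fish |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      fish_richness = dplyr::n_distinct(.data$species),
      fish_total_biomass_g = sum(.data$biomass_g) / n_cyl,
      fish_commercial_biomass_g = sum(.data$biomass_g[.data$commercial]) / n_cyl)

  benthic <- survey$benthic |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      coral_cover_pct = mean(.data$coral) / pts * 100,
      coral_macroalgal_ratio = (sum(.data$coral) + 0.5) /
        (sum(.data$macroalgae) + 0.5))

  coral_rich <- survey$coral_species |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(coral_richness = dplyr::n_distinct(.data$species))

  sites |>
    dplyr::select("site_id", "zone", "type") |>
    dplyr::left_join(by_site, by = "site_id") |>
    dplyr::left_join(benthic, by = "site_id") |>
    dplyr::left_join(coral_rich, by = "site_id") |>
    dplyr::mutate(dplyr::across(
      c("fish_richness", "fish_total_biomass_g", "fish_commercial_biomass_g",
        "coral_richness"),
      ~ tidyr::replace_na(.x, 0)))
}

#' Per-species site biomass table
#'
#' Site x species biomass (g, cylinder-averaged), the input to Bray-Curtis
#' dissimilarities, ANOSIM and the species-level reserve screen.
#'
#' @inheritParams summarize_responses
#' @return A wide tibble: `site_id`, then one biomass column per species
#'   (every species in `species` present, zero-filled).
#' @export
species_biomass_matrix <- function(survey, species) {
  n_cyl <- survey$design$n_cylinders
  long <- survey$fish |>
    dplyr::left_join(tibble::as_tibble(species)[, c("species", "a", "b")],
                     by = "species") |>
    dplyr::mutate(biomass_g = allometric_biomass(.data$fork_length_cm,
                                                 .data$a, .data$b) * .data$count) |>
    dplyr::group_by(.data$site_id, .data$species) |>
    dplyr::summarise(biomass_g = sum(.data$biomass_g) / n_cyl, .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "species",
                             values_from = "biomass_g", values_fill = 0)
  all_sp <- setdiff(tibble::as_tibble(species)$species, names(wide))
  for (s in all_sp) wide[[s]] <- 0
  miss_sites <- setdiff(survey$sites$site_id, wide$site_id)
  if (length(miss_sites)) {
    pad <- wide[0, ]
    pad[seq_along(miss_sites), "site_id"] <- miss_sites
    pad[is.na(pad)] <- 0
    wide <- dplyr::bind_rows(wide, pad)
  }
  ord <- c("site_id", sort(setdiff(names(wide), "site_id")))
  wide[match(survey$sites$site_id, wide$site_id), ord]
}

#' @export
print.survey_data <- function(x, ...) {
  cat(sprintf("<survey_data> %d sites; %d fish records; %d benthic images\n",
              nrow(x$sites), nrow(x$fish), nrow(x$benthic)))
  invisible(x)
}
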