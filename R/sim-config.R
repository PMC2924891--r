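#' Configuration for the synthetic lagoon simulator
#'
#' Bundles every tunable of the seascape and survey simulator. Defaults
#' emulate a Caribbean atoll patch-reef lagoon: elliptical patch
#' reefs of 20-10,000 m^2 scattered over a sand/seagrass lagoon floor that
#' slopes from 6 to 18 m, rising to within 0.5-3 m of the surface; a no-take
#' reserve occupying one sector; two channel passes through the atoll rim;
#' and two latent seascape types - Type I patches far from channels, large,
#' isolated and dome-shaped, Type II patches near channels, small, densely
#' arrayed and structurally complex. Surveys follow the standard protocol:
#' five 5 m-diameter point-count cylinders per site for fish, and 20 benthic
#' images scored at 100 random points each for cover.
#'
#' Reserve effects are planted per response and per latent type on the log
#' (fish counts) or log-odds (benthic cover) scale; the defaults reproduce a
#' mixed-sign response pattern: commercial fish biomass up 75% and total
#' biomass up ~50% on Type II patches only, coral cover down 65% on Type I
#' but up 68% on Type II, with the coral:macroalgal ratio moving -57%/+80%.
#' Pooled over a lagoon with both types these contrasts largely cancel -
#' the masking phenomenon the stratified assessment is designed to expose.
#'
#' @param lagoon_width_m,lagoon_height_m lagoon extent, metres.
#' @param cell_size_m raster resolution (default 4, a 4x4 m ground cell).
#' @param n_patches number of patch reefs to place (>= 2 unless 0 for an
#'   empty scene).
#' @param patch_area_range_m2 global log-uniform area range, m^2.
#' @param type1_area_range_m2,type2_area_range_m2 per-type sub-ranges.
#' @param p_type2 probability a patch is latent Type II.
#' @param type2_channel_annulus_m radial band (m) around a channel in
#'   which Type II patches are placed (area-uniform within the annulus);
#'   channels inside the reserve polygon collectively receive weight
#'   `reserve_fraction` so that the Type II share is balanced across
#'   zones. Type I centres are rejected within `type1_channel_buffer_m`
#'   of any channel, giving the two types disjoint isolation/channel
#'   gradients.
#' @param type1_channel_buffer_m see above.
#' @param type1_min_spacing_m minimum centre-to-centre distance between
#'   Type I patches, enforcing the isolation ("more isolated, larger
#'   nearest-neighbor distance") that distinguishes the open-lagoon type.
#' @param reserve_fraction fraction of lagoon width/height in the reserve.
#' @param reserve_sector one of "west", "east", "south", "north".
#' @param channel_coords,mangrove_coords feature coordinates, a 2-column
#'   (x, y) matrix in metres; `NULL` places two channels on opposite rim
#'   edges and a mangrove stand at the SE corner.
#' @param depth_range_m lagoon-floor depth range (shallow edge to deep edge).
#' @param patch_top_depth_m range of patch-top depths below the surface.
#' @param n_sites number of patches surveyed (sampled without replacement).
#' @param n_cylinders_per_site,cylinder_diameter_m fish survey design.
#' @param n_images_per_site,points_per_image benthic photo design.
#' @param n_fine_rugosity_reps chain-transect replicates per site.
#' @param species species table (see [default_species_table()]).
#' @param beta_fish named log-scale coefficients on standardized covariates
#'   `distance_from_channel_km`, `reef_area_500m_m2`, `nearest_neighbor_m`.
#' @param beta_coral named log-odds coefficients on standardized
#'   `patch_size` (log area), `distance_from_channel_km`,
#'   `structural_complexity`.
#' @param delta_fish list with elements `commercial` and `noncommercial`,
#'   each `c(type1=, type2=)` log-scale reserve multipliers on counts.
#' @param delta_coral_cover,delta_coral_richness,delta_macroalgae
#'   `c(type1=, type2=)` reserve effects (log-odds for covers, log for
#'   richness).
#' @param coral_cover_baseline,macroalgae_baseline,turf_baseline,
#'   cca_baseline mean benthic cover fractions on control Type I patches.
#' @param sand_fraction_mean,sand_fraction_sd per-patch sand/seagrass
#'   fraction of the patch footprint (Beta-distributed), used for the
#'   hard-substrate area adjustment.
#' @param sigma_site_fish,sigma_coral,sigma_length lognormal site effect on
#'   fish counts, logit-scale site noise on covers, and lognormal length sd.
#' @param coral_richness_mean mean stony-coral richness per control site.
#' @param fine_rugosity_range type-wise ranges of true fine rugosity,
#'   a list with `type1` and `type2` 2-vectors.
#' @param rng_seed integer seed; every stage derives its own child seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patches = 20, n_sites = 10, rng_seed = 7)
#' cfg$n_patches
#' @export
sim_config <- function(
    lagoon_width_m = 2000, lagoon_height_m = 2000, cell_size_m = 4,
    n_patches = 95,
    patch_area_range_m2 = c(20, 10000),
    type1_area_range_m2 = c(800, 8000),
    type2_area_range_m2 = c(20, 1000),
    p_type2 = 0.5,
    type2_channel_annulus_m = c(120, 450),
    type1_channel_buffer_m = 700,
    type1_min_spacing_m = 160,
    reserve_fraction = 0.35, reserve_sector = "west",
    channel_coords = NULL, mangrove_coords = NULL,
    depth_range_m = c(6, 18), patch_top_depth_m = c(0.5, 3),
    n_sites = 87,
    n_cylinders_per_site = 5, cylinder_diameter_m = 5,
    n_images_per_site = 20, points_per_image = 100,
    n_fine_rugosity_reps = 5,
    species = default_species_table(),
    beta_fish = c(distance_from_channel_km = -0.45,
                  reef_area_500m_m2 = 0.10,
                  nearest_neighbor_m = -0.20),
    beta_coral = c(patch_size = -0.20,
                   distance_from_channel_km = -0.23,
                   structural_complexity = 0.26),
    delta_fish = list(commercial    = c(type1 = 0, type2 = log(1.75)),
                      noncommercial = c(type1 = 0, type2 = log(1.25))),
    delta_coral_cover    = c(type1 = log(0.35), type2 = log(1.68)),
    delta_coral_richness = c(type1 = 0,          type2 = log(0.83)),
    delta_macroalgae     = c(type1 = log(0.81),  type2 = log(0.93)),
    coral_cover_baseline = 0.20, macroalgae_baseline = 0.16,
    turf_baseline = 0.22, cca_baseline = 0.08,
    sand_fraction_mean = 0.28, sand_fraction_sd = 0.08,
    sigma_site_fish = 0.30, sigma_coral = 0.30, sigma_length = 0.18,
    coral_richness_mean = 16,
    fine_rugosity_range = list(type1 = c(1.2, 1.6), type2 = c(1.5, 2.1)),
    rng_seed = 1L) {

  assert_positive(c(lagoon_width_m, lagoon_height_m, cell_size_m), "lagoon dims")
  if (n_patches < 0 || (n_patches != 0 && n_patches < 2))
    abort("`n_patches` must be 0 or >= 2.")
  assert_positive(patch_area_range_m2, "patch_area_range_m2")
  stopifnot(patch_area_range_m2[1] < patch_area_range_m2[2])
  for (r in list(type1_area_range_m2, type2_area_range_m2))
    if (r[1] < patch_area_range_m2[1] - 1e-9 || r[2] > patch_area_range_m2[2] + 1e-9)
      abort("Type area ranges must lie within `patch_area_range_m2`.")
  assert_fraction(reserve_fraction, "reserve_fraction", closed = FALSE)
  assert_fraction(p_type2, "p_type2")
  reserve_sector <- match.arg(reserve_sector, c("west", "east", "south", "north"))
  if (is.null(channel_coords))
    channel_coords <- rbind(c(0, 0.30 * lagoon_height_m),
                            c(lagoon_width_m, 0.70 * lagoon_height_m))
  if (is.null(mangrove_coords))
    mangrove_coords <- rbind(c(lagoon_width_m, 0))
  channel_coords <- as_coord_matrix(channel_coords, "channel_coords")
  mangrove_coords <- as_coord_matrix(mangrove_coords, "mangrove_coords")
  stopifnot(depth_range_m[1] > 0, diff(depth_range_m) >= 0,
            all(patch_top_depth_m >= 0), n_sites >= 1)
  species <- validate_species_table(species)

  structure(mget(names(formals(sim_config)), envir = environment()),
            class = "sim_config")
}

as_coord_matrix <- function(x, name) {
  x <- rbind(x)
  if (!is.numeric(x) || ncol(x) != 2 || nrow(x) < 1)
    abort(sprintf("`%s` must be an n x 2 numeric (x, y) matrix.", name))
  colnames(x) <- c("x", "y")
  x
}

#' Default simulated fish species pool
#'
#' Twenty reef-fish species with allometric coefficients (mass in g from
#' fork length in cm via a * L^b), lognormal length distributions, relative
#' log-abundance intercepts, and a commercial flag marking fishery-targeted
#' species. Coefficient values are typical published reef-fish magnitudes;
#' they are inputs, not constants of the method.
#'
#' @param n_species number of species (recycled over the template pool).
#' @param n_commercial how many of them are flagged commercial.
#' @return A tibble with columns `species`, `commercial`, `a`, `b`,
#'   `meanlog_length`, `log_abundance`.
#' @export
default_species_table <- function(n_species = 20, n_commercial = 8) {
  stopifnot(n_species >= 1, n_commercial <= n_species)
  i <- seq_len(n_species)
  tibble::tibble(
    species = sprintf("sp%02d", i),
    commercial = i <= n_commercial,
    # deterministic spread of plausible allometries, no RNG involved
    a = round(0.008 + 0.022 * ((i * 7) %% n_species) / n_species, 5),
    b = round(2.85 + 0.25 * ((i * 3) %% n_species) / n_species, 3),
    meanlog_length = log(12) + 0.5 * ((i * 5) %% n_species) / n_species,
    # commercial species get larger intercepts so that they carry roughly
    # half of the total biomass at the default pool
    log_abundance = log(1.6) + ifelse(i <= n_commercial, 0.45, 0) -
      0.9 * (i - 1) / n_species)
}

validate_species_table <- function(sp) {
  sp <- tibble::as_tibble(sp)
  need <- c("species", "commercial", "a", "b", "meanlog_length",
            "log_abundance")
  miss <- setdiff(need, names(sp))
  if (length(miss)) abort(paste("species table lacks:", paste(miss, collapse = ", ")))
  assert_positive(sp$a, "a"); assert_positive(sp$b, "b")
  if (anyDuplicated(sp$species)) abort("Duplicate species names.")
  sp
}

#' Allometric length-to-mass conversion
#'
#' Standard power-law conversion mass = a * length^b with species-specific
#' coefficients; lengths in cm fork length, mass in g.
#'
#' @param length_cm fish fork length(s), cm; must be positive.
#' @param a,b allometric coefficients; must be positive.
#' @return Mass in grams, vectorized over inputs.
#' @examples
#' allometric_biomass(10, 0.01, 3) # 10 g
#' @export
allometric_biomass <- function(length_cm, a, b) {
  assert_positive(length_cm, "length_cm")
  assert_positive(a, "a"); assert_positive(b, "b")
  a * length_cm^b
}
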