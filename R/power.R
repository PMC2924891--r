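#' Pooled versus stratified assessment power experiment
#'
#' Monte-Carlo power comparison of the two Control-Impact designs over
#' full simulate -> metrics -> cluster -> assess cycles: each replicate
#' draws a fresh seascape and survey from `config`, computes the seascape
#' metrics, classifies sites into `k` groups for each community
#' (clustering on the configured fish metrics and on distance from
#' channel + patch-size PC1 + structural complexity for corals), and
#' records per-response p-values for the pooled contrast and for the
#' stratified contrasts. The stratified decision per replicate uses the
#' minimum Bonferroni-adjusted p across tested strata, so that under a
#' null simulation both designs reject at about `alpha`.
#'
#' @param config a [sim_config()]; its planted effects define the
#'   alternative being powered.
#' @param n_replicates number of Monte-Carlo replicates (>= 50 for stable
#'   estimates; smaller values are allowed but warn).
#' @param seed master seed; replicate r uses an independent child seed.
#' @param alpha test level (default 0.05).
#' @param k groups per community (default 2).
#' @param new_scene_each_rep redraw the seascape every replicate
#'   (default TRUE); FALSE redraws only the surveys on one fixed scene.
#' @return A `power_table` tibble: `response`, `design`
#'   ("pooled"/"stratified"), `power`, `n_replicates`, `alpha`; per-rep
#'   p-value matrices and mean type-recovery ARIs are attached as
#'   attributes `p_values` and `ari`.
#' @export
power_experiment <- function(config, n_replicates = 200, seed = 1L,
                             alpha = 0.05, k = 2,
                             new_scene_each_rep = TRUE) {
  if (n_replicates < 50)
    warn("Fewer than 50 replicates gives unstable power estimates.")
  resp <- response_columns()
  p_pool <- p_strat <- matrix(NA_real_, n_replicates, length(resp),
                              dimnames = list(NULL, resp))
  ari_fish <- ari_coral <- rep(NA_real_, n_replicates)
  scene0 <- if (!new_scene_each_rep) {
    cfg0 <- config; cfg0$rng_seed <- child_seed(seed, "scene0")
    generate_seascape(cfg0)
  }
  for (rep_i in seq_len(n_replicates)) {
    cfg <- config
    cfg$rng_seed <- child_seed(seed, paste0("rep", rep_i))
    scene <- if (new_scene_each_rep) generate_seascape(cfg) else scene0
    met <- seascape_metrics(scene, buffers = 500)
    survey <- simulate_communities(scene, met, cfg, seed = cfg$rng_seed)
    responses <- summarize_responses(survey, cfg$species)
    env <- build_env_matrix(met)
    groups <- power_groupings(env, met, k)
    ari_fish[rep_i] <- adjusted_rand_index(groups$fish$group,
                                           scene$sites$type)
    ari_coral[rep_i] <- adjusted_rand_index(groups$coral$group,
                                            scene$sites$type)
    sites <- site_records(responses, groups$fish, groups$coral)
    pooled <- pooled_ci(sites)
    p_pool[rep_i, pooled$response] <- pooled$p_value
    for (comm in c("fish", "coral")) {
      rv <- grep(paste0("^", comm), resp, value = TRUE)
      st <- stratified_ci(sites, comm, responses = rv)
      for (r in rv) {
        ps <- st$p_value[st$response == r & st$tested]
        if (length(ps))
          p_strat[rep_i, r] <- min(pmin(ps * length(ps), 1))
      }
    }
  }
  pow <- dplyr::bind_rows(
    tibble::tibble(response = resp, design = "pooled",
                   power = colMeans(p_pool < alpha, na.rm = TRUE)),
    tibble::tibble(response = resp, design = "stratified",
                   power = colMeans(p_strat < alpha, na.rm = TRUE)))
  pow$n_replicates <- n_replicates
  pow$alpha <- alpha
  structure(pow, class = c("power_table", class(pow)),
            p_values = list(pooled = p_pool, stratified = p_strat),
            ari = c(fish = mean(ari_fish), coral = mean(ari_coral)),
            seed = seed)
}

# the two community-specific clusterings used in power replicates: the
# configured fish metrics, and for corals distance from channel +
# patch-size PC1 (over the collinear size block) + structural complexity
power_groupings <- function(env, met, k) {
  fish_cols <- intersect(fish_metric_columns(), names(env))
  coral_env <- env["site_id"]
  coral_env$distance_from_channel_km <- env$distance_from_channel_km
  size_cols <- intersect(size_metric_columns(), names(env))
  coral_env$patch_size <- if (length(size_cols) >= 2)
    zscore(pca_collapse(env, size_cols)$scores) else env[[size_cols[1]]]
  coral_env$structural_complexity <- env$structural_complexity
  list(fish = cluster_sites(env, fish_cols, k = k),
       coral = cluster_sites(coral_env, setdiff(names(coral_env), "site_id"),
                             k = k))
}

#' @export
print.power_table <- function(x, ...) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x)[c("response", "design", "power")],
                             names_from = "design", values_from = "power")
  cat(sprintf("<power_table> %d replicates, alpha = %.2f\n",
              x$n_replicates[1], x$alpha[1]))
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}
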