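#' Variable transformations for metrics and responses
#'
#' The transformation vocabulary used across the pipeline: `log10` for
#' right-skewed distances/areas, `arcsine_sqrt` for proportion (% cover)
#' data, `boxcox` with the power parameter fitted by profile maximum
#' likelihood on a lambda grid of `[-3, 3]` in steps of 0.01, `fourth_root`
#' for abundance down-weighting, or `none`. Domain violations fail naming
#' the offending positions; zeros under `log10`/`boxcox` are an error
#' unless a positive `offset` is supplied.
#'
#' @param values numeric vector.
#' @param method one of "log10", "arcsine_sqrt", "boxcox", "fourth_root",
#'   "none".
#' @param offset added before log/Box-Cox transforms (default 0).
#' @return Transformed vector; for `boxcox`, the fitted lambda is attached
#'   as attribute `lambda`.
#' @examples
#' transform_values(c(0.25), "arcsine_sqrt") # pi/6
#' transform_values(16, "fourth_root")       # 2
#' @export
transform_values <- function(values,
                             method = c("none", "log10", "arcsine_sqrt",
                                        "boxcox", "fourth_root"),
                             offset = 0) {
  method <- match.arg(method)
  x <- values + if (method %in% c("log10", "boxcox")) offset else 0
  bad_at <- function(ok, what) {
    if (all(ok)) return(invisible())
    abort(sprintf("%s at positions: %s", what,
                  paste(head(which(!ok), 5), collapse = ", ")))
  }
  switch(method,
    none = values,
    log10 = { bad_at(x > 0, "log10 of non-positive values"); log10(x) },
    fourth_root = { bad_at(x >= 0, "fourth root of negative values"); x^0.25 },
    arcsine_sqrt = {
      bad_at(x >= 0 & x <= 1, "arcsine-sqrt outside [0, 1]")
      asin(sqrt(x))
    },
    boxcox = {
      bad_at(x > 0, "Box-Cox of non-positive values")
      bc <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
      lam <- bc$x[which.max(bc$y)]
      out <- if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
      attr(out, "lambda") <- lam
      out
    })
}

#' Default transformation map for the seascape metric table
#'
#' Distances, isolation, buffer areas, patch areas and perimeter are
#' log10-transformed; the edge:area ratio and bathymetric volume are
#' Box-Cox; volumes/surfaces estimated from rugosity and the structure
#' indices are left untransformed.
#' @return Named character vector: metric column -> method.
#' @export
default_metric_transforms <- function() {
  c(distance_from_channel_km = "log10", distance_to_mangroves_km = "log10",
    nearest_neighbor_m = "log10",
    reef_area_1km_m2 = "log10", reef_area_500m_m2 = "log10",
    reef_area_200m_m2 = "log10",
    area_m2 = "log10", area_hard_substrate_m2 = "log10",
    perimeter_m = "log10", edge_area_ratio = "boxcox",
    estimated_volume_m3 = "none", bathymetric_volume_m3 = "boxcox",
    surface_area_m2 = "none",
    fine_rugosity = "none", coarse_rugosity = "none",
    structural_complexity = "none")
}

#' Build a standardized environmental matrix from the metric table
#'
#' Applies the per-metric transformation map, then standardizes each column
#' to zero mean and unit variance (canonical coefficients are otherwise
#' scale-dependent). Buffer areas of zero are guarded with a half-cell
#' offset before log10.
#'
#' @param metrics metric tibble from [seascape_metrics()].
#' @param transforms named vector (column -> method); defaults to
#'   [default_metric_transforms()], restricted to columns present.
#' @return Tibble `site_id` + standardized metric columns, with attributes
#'   `transforms` and `boxcox_lambda`.
#' @export
build_env_matrix <- function(metrics, transforms = default_metric_transforms()) {
  cols <- intersect(names(transforms), names(metrics))
  out <- metrics["site_id"]
  lambdas <- c()
  for (cn in cols) {
    x <- metrics[[cn]]
    off <- if (transforms[[cn]] %in% c("log10", "boxcox") && any(x <= 0))
      max(min(x[x > 0], na.rm = TRUE) / 2, 1e-6) else 0
    tx <- transform_values(x, transforms[[cn]], offset = off)
    if (!is.null(attr(tx, "lambda"))) lambdas[cn] <- attr(tx, "lambda")
    out[[cn]] <- zscore(as.numeric(tx))
  }
  attr(out, "transforms") <- transforms[cols]
  attr(out, "boxcox_lambda") <- lambdas
  out
}

#' Group collinear metrics by a correlation screen
#'
#' Builds a graph over metric columns with an edge wherever the absolute
#' Pearson correlation exceeds `threshold`, and returns its connected
#' components: metrics in one component are treated as a collinear block
#' (transitive closure), singletons pass through untouched.
#'
#' @param env environmental tibble (standardized metrics; `site_id`
#'   column ignored).
#' @param threshold correlation magnitude above which columns are linked
#'   (default 0.2).
#' @return A list with `groups` (list of column-name vectors, multi-member
#'   groups first) and the correlation matrix `r`.
#' @export
correlation_screen <- function(env, threshold = 0.2) {
  m <- as.matrix(env[setdiff(names(env), "site_id")])
  if (ncol(m) < 2) abort("Need at least two metric columns.")
  r <- cor(m)
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(colnames(m), comp)
  groups <- groups[order(-lengths(groups), vapply(groups, `[`, "", 1))]
  list(groups = unname(groups), r = r)
}

#' Collapse a collinear block to its first principal component
#'
#' Eigen-decomposition of the correlation matrix of the block; PC1 scores
#' are returned with the sign fixed so that PC1 correlates positively with
#' the first input column, along with its variance share.
#'
#' @param env environmental tibble.
#' @param cols columns forming the collinear block (>= 2).
#' @return List: `scores` (n-vector), `variance_share` (fraction), `loadings`.
#' @export
pca_collapse <- function(env, cols) {
  if (length(cols) < 2) abort("PCA collapse needs >= 2 columns.")
  m <- scale(as.matrix(env[cols]))
  ev <- eigen(cor(m), symmetric = TRUE)
  scores <- drop(m %*% ev$vectors[, 1])
  if (cor(scores, m[, 1]) < 0) { scores <- -scores; ev$vectors[, 1] <- -ev$vectors[, 1] }
  list(scores = scores,
       variance_share = ev$values[1] / sum(ev$values),
       loadings = setNames(ev$vectors[, 1], cols))
}

#' Apply the correlation screen and collapse every collinear block
#'
#' @param env environmental tibble.
#' @param threshold passed to [correlation_screen()].
#' @param names_for optional named list mapping a composite name (e.g.
#'   `patch_size`) to the columns it should replace; blocks not matched get
#'   a name made from their first member (`<col>_PC1`).
#' @return List: `env` (reduced tibble), `blocks` (tibble describing each
#'   collapsed block and its PC1 variance share).
#' @export
collapse_collinear <- function(env, threshold = 0.2, names_for = list()) {
  scr <- correlation_screen(env, threshold)
  out <- env["site_id"]
  blocks <- list()
  for (g in scr$groups) {
    if (length(g) == 1) { out[[g]] <- env[[g]]; next }
    pc <- pca_collapse(env, g)
    nm <- names(names_for)[vapply(names_for, function(v) setequal(g, v), TRUE)]
    nm <- if (length(nm)) nm[1] else paste0(g[1], "_PC1")
    out[[nm]] <- zscore(pc$scores)
    blocks[[nm]] <- tibble::tibble(
      component = nm, members = paste(g, collapse = "+"),
      variance_share = pc$variance_share)
  }
  list(env = out, blocks = dplyr::bind_rows(blocks), screen = scr)
}
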