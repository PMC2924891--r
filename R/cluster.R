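#' Classify sites into seascape groups by hierarchical clustering
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage via
#' `hclust(method = "ward.D2")`) of the standardized seascape metrics
#' selected for a community, cut at `k` groups. Ward linkage is the
#' default because it favours compact, balanced groups and so keeps
#' within-group sample sizes workable for the stratified contrasts; the
#' linkage is a configuration knob. Group labels are Roman numerals
#' ordered by the group mean of `order_by` (descending by default, so
#' with the default column Type I is the group further from channels).
#' Merge-height ties inherit `hclust`'s deterministic lowest-index
#' ordering.
#'
#' @param env standardized metric tibble (`site_id` + metric columns).
#' @param cols columns to cluster on (default: all metric columns).
#' @param k number of groups (default 2).
#' @param method linkage passed to [stats::hclust()].
#' @param order_by column whose descending group mean orders the labels;
#'   defaults to `distance_from_channel_km` when present, else the first
#'   clustering column.
#' @return A `cluster_assignment`: tibble `site_id`, `group` (factor
#'   "I", "II", ...), with the `hclust` tree, `k` and clustering columns
#'   as attributes.
#' @export
cluster_sites <- function(env, cols = NULL, k = 2, method = "ward.D2",
                          order_by = NULL) {
  cols <- cols %||% setdiff(names(env), "site_id")
  miss <- setdiff(cols, names(env))
  if (length(miss)) abort(paste("Unknown columns:", paste(miss, collapse = ", ")))
  m <- as.matrix(env[cols])
  rownames(m) <- env$site_id
  if (nrow(m) < k) abort("Need at least k sites.")
  hc <- hclust(dist(m), method = method)
  raw <- cutree(hc, k = k)
  order_by <- order_by %||%
    (if ("distance_from_channel_km" %in% cols) "distance_from_channel_km"
     else cols[1])
  gmeans <- tapply(env[[order_by]], raw, mean)
  new_order <- order(-gmeans)
  relabel <- match(seq_len(k), new_order)
  lab <- as.roman(relabel[raw])
  out <- tibble::tibble(site_id = env$site_id,
                        group = factor(as.character(lab),
                                       levels = as.character(as.roman(seq_len(k)))))
  structure(out, hclust = hc, k = k, cols = cols, order_by = order_by,
            class = c("cluster_assignment", class(out)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected partition agreement (1 = identical, ~0 = random),
#' used to verify that the clustering recovers planted seascape types.
#' Thin wrapper around `mclust::adjustedRandIndex()`.
#'
#' @param a,b partition labels of equal length.
#' @return ARI scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
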