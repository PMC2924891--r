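#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns per-component rows (canonical axes for a CCA fit,
#' selection steps for a forward selection, sites for a clustering,
#' factors for an ANOSIM); `glance()` returns a one-row model summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return A tibble.
#' @name seascapeCI-tidiers
NULL

#' @rdname seascapeCI-tidiers
#' @export
tidy.cca_fit <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eig), eigenvalue = x$eig,
                 prop_total_inertia = x$eig / x$total_inertia)
}

#' @rdname seascapeCI-tidiers
#' @export
glance.cca_fit <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, rank = x$rank,
                 total_inertia = x$total_inertia,
                 constrained_inertia = x$constrained_inertia,
                 prop_axis1 = x$prop_axis1, pseudo_F = x$pseudo_F,
                 p_value = x$p_value %||% NA_real_,
                 n_perm = x$n_perm %||% NA_integer_)
}

#' @rdname seascapeCI-tidiers
#' @export
tidy.cca_select <- function(x, ...) x$trace

#' @rdname seascapeCI-tidiers
#' @export
glance.cca_select <- function(x, ...) {
  dplyr::mutate(
    if (is.null(x$fit)) tibble::tibble(pseudo_F = NA_real_, p_value = NA_real_)
    else glance(x$fit)[c("pseudo_F", "p_value")],
    n_selected = length(x$selected),
    selected = paste(x$selected, collapse = "+"),
    total_inertia = x$total_inertia)
}

#' @rdname seascapeCI-tidiers
#' @export
tidy.cluster_assignment <- function(x, ...) tibble::as_tibble(x)

#' @rdname seascapeCI-tidiers
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"),
                 n_sites = nrow(x),
                 columns = paste(attr(x, "cols"), collapse = "+"),
                 smallest_group = min(table(x$group)))
}

#' @rdname seascapeCI-tidiers
#' @export
tidy.anosim_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname seascapeCI-tidiers
#' @export
tidy.assessment_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$pooled), community = "pooled"),
    dplyr::mutate(tibble::as_tibble(x$stratified_fish), community = "fish"),
    dplyr::mutate(tibble::as_tibble(x$stratified_coral), community = "coral"))
}
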