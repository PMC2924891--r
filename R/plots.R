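#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_path geom_point
#'   geom_col geom_hline facet_wrap labs scale_fill_manual coord_equal
#'   theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot a simulated seascape scene
#'
#' Habitat classes as a raster with the reserve boundary, channel points,
#' and patch centroids colored by latent type.
#'
#' @param object a `seascape_scene`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.seascape_scene <- function(object, ...) {
  hab <- object$habitat
  ctr <- cell_centers(hab)
  df <- tidyr::expand_grid(y = ctr$y, x = ctr$x)
  df$class <- factor(names(hab$class_map)[match(as.vector(t(hab$values)),
                                                hab$class_map)],
                     levels = names(hab$class_map))
  res <- as.data.frame(rbind(object$reserve_polygon,
                             object$reserve_polygon[1, ]))
  names(res) <- c("x", "y")
  ch <- as.data.frame(object$channels)
  ggplot(df, aes(.data$x, .data$y)) +
    geom_raster(aes(fill = .data$class)) +
    scale_fill_manual(values = c(sand = "#f2e3c0", seagrass = "#9fc49a",
                                 reef = "#c96a4a")) +
    geom_path(data = res, linewidth = 0.8, colour = "navy") +
    geom_point(data = ch, shape = 4, size = 3, stroke = 1.5) +
    geom_point(data = object$patches, aes(colour = .data$type), size = 0.6) +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)", fill = "habitat", colour = "latent type",
         title = "Simulated lagoon seascape") +
    theme_minimal()
}

#' Plot reserve effect sizes by stratum
#'
#' Percent difference (outside baseline) per response and stratum, with
#' untested gap strata omitted.
#'
#' @param object an `effect_table` (or `tidy()` of an assessment report
#'   with a `community` column).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.effect_table <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$tested)
  ggplot(df, aes(.data$response, .data$pct_diff_outside,
                 fill = .data$stratum)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(y = "% difference inside vs outside (outside baseline)",
         x = NULL, fill = "stratum") +
    theme_minimal()
}

#' Plot pooled versus stratified power
#'
#' @param object a `power_table` from [power_experiment()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.power_table <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(.data$response, .data$power, fill = .data$design)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_hline(yintercept = object$alpha[1], linetype = 2, linewidth = 0.3) +
    labs(y = sprintf("rejection rate at alpha = %.2f", object$alpha[1]),
         x = NULL) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
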