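#' Plot a gap-statistic profile
#'
#' Gap value per candidate k with one-standard-error bars; the selected
#' `k_opt` is highlighted.
#'
#' @param object A `poolnet_gap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poolnet_gap <- function(object, ...) {
  prof <- object$profile
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$gap - .data$se,
                                        ymax = .data$gap + .data$se),
                           width = 0.15, colour = "grey55") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = prof[prof$k == object$k_opt, ],
                        colour = "firebrick", size = 3) +
    ggplot2::scale_x_continuous(breaks = prof$k) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic",
                  title = sprintf("Gap profile (k_opt = %d)", object$k_opt)) +
    ggplot2::theme_minimal()
}

#' Map species range centroids coloured by group
#'
#' The visual counterpart of the spatial-clustering test: centroids of
#' species in the same group should sit close together when the grouping is
#' spatially structured.
#'
#' @param centroids Tibble from [species_centroids()].
#' @param partition A partition of the centroid species.
#' @return A ggplot object.
#' @export
plot_centroids <- function(centroids, partition) {
  p <- as_partition(partition)
  df <- dplyr::inner_join(centroids, tidy(p), by = "species")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_km, y = .data$y_km,
                                   colour = factor(.data$group))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", colour = "group") +
    ggplot2::theme_minimal()
}

#' Density plot of co-occurrence effect sizes by pair set
#'
#' Compares the distribution of standardized effect sizes for host-associate
#' pairs, within-group pairs and among-group pairs — large positive complex
#' effects against a near-zero network background indicate that the complex
#' is more than a habitat signal.
#'
#' @param effects Effect table from [effect_size_table()].
#' @param net A `poolnet_network`.
#' @param partition A partition covering the network's nodes.
#' @param complex A [nest_complex()].
#' @return A ggplot object.
#' @export
plot_effect_density <- function(effects, net, partition, complex) {
  p <- as_partition(partition)
  nodes <- igraph::V(as_igraph(net))$name
  eff <- effects[effects$species_a %in% nodes & effects$species_b %in% nodes, ]
  key <- paste(pmin(eff$species_a, eff$species_b), pmax(eff$species_a, eff$species_b))
  complex_keys <- paste(pmin(complex$host, complex$associates),
                        pmax(complex$host, complex$associates))
  eff$pair_set <- ifelse(key %in% complex_keys, "nest associates",
                         ifelse(unclass(p)[eff$species_a] == unclass(p)[eff$species_b],
                                "within group", "among group"))
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$effect, fill = .data$pair_set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "standardized co-occurrence effect size", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
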