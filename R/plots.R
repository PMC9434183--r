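#' Heatmap of log2 stage means
#'
#' Tile heatmap of the compound-by-stage matrix from [log2_stage_means()],
#' with compound rows ordered by hierarchical clustering (Euclidean distance,
#' complete linkage) as is conventional for developmental heatmaps.
#'
#' @param means Wide tibble from [log2_stage_means()].
#' @param cluster_rows Reorder rows by hierarchical clustering.
#' @return A ggplot object.
#' @export
plot_stage_heatmap <- function(means, cluster_rows = TRUE) {
  m <- as.matrix(means[, -1])
  rownames(m) <- means$compound
  if (cluster_rows && nrow(m) > 2) {
    ord <- hclust(dist(m), method = "complete")$order
    m <- m[ord, , drop = FALSE]
  }
  long <- tibble::as_tibble(m, rownames = "compound") |>
    tidyr::pivot_longer(-"compound", names_to = "stage", values_to = "log2_mean")
  long$compound <- factor(long$compound, levels = rev(rownames(m)))
  long$stage <- factor(long$stage, levels = colnames(m))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$compound,
                                     fill = .data$log2_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b",
                                  midpoint = mean(long$log2_mean, na.rm = TRUE)) +
    ggplot2::labs(x = "stage", y = NULL, fill = "log2 mean") +
    ggplot2::theme_minimal()
}

#' Boxplots of abundance relative to the youngest stage
#'
#' @param rel Long table from [relative_to_reference()].
#' @param compounds Optional subset of compounds to show.
#' @return A ggplot object (one facet per compound).
#' @export
plot_relative_profiles <- function(rel, compounds = NULL) {
  if (!is.null(compounds)) rel <- rel[rel$compound %in% compounds, ]
  ggplot2::ggplot(rel, ggplot2::aes(x = factor(.data$stage), y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::labs(x = "stage", y = "abundance relative to youngest stage") +
    ggplot2::theme_minimal()
}

#' Plot a correlation network
#'
#' Draws the thresholded correlation network with node size mapped to
#' betweenness centrality and edge alpha to |r|, using a force-directed
#' layout computed with igraph.
#'
#' @param object A `correlation_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_network <- function(object, ...) {
  if (!nrow(object$edges)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(object$edges[, c("source", "target")],
                                     directed = FALSE)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nodes <- dplyr::left_join(object$nodes, lay, by = "id")
  edges <- object$edges |>
    dplyr::left_join(lay, by = c(source = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c(target = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       alpha = abs(.data$r)),
                          color = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$betweenness,
                                     color = .data$class)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "betweenness", color = "class", alpha = "|r|")
}

#' Cluster centroid profiles across stages
#'
#' @param clusters A `profile_clusters` object from [kmeans_profiles()].
#' @return A ggplot object of the standardised centroid per cluster.
#' @export
plot_cluster_centroids <- function(clusters) {
  long <- tidyr::pivot_longer(clusters$centroids, -"cluster",
                              names_to = "stage", values_to = "z")
  long$stage <- factor(long$stage, levels = setdiff(names(clusters$centroids),
                                                    "cluster"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$z,
                                     group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "stage", y = "standardised expression") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
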