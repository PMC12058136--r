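#' Plot a disease network
#'
#' Basic static plot: nodes on a deterministic Fruchterman-Reingold layout,
#' edge width proportional to |weight|, dashed edges for negative
#' associations, nodes coloured by community when a partition is given.
#'
#' @param net A [pairwise_network()].
#' @param partition Optional `community_partition`.
#' @param layout_seed Seed for the layout (plot aesthetics only).
#' @return A ggplot object.
#' @export
plot_network <- function(net, partition = NULL, layout_seed = 1) {
  g <- as_igraph(net)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(disease = net$nodes, x = xy[, 1], y = xy[, 2])
  if (!is.null(partition)) {
    nodes$community <- factor(partition$membership$community[
      match(nodes$disease, partition$membership$disease)])
  }
  edges <- net$edges
  edges$x <- nodes$x[match(edges$from, nodes$disease)]
  edges$y <- nodes$y[match(edges$from, nodes$disease)]
  edges$xend <- nodes$x[match(edges$to, nodes$disease)]
  edges$yend <- nodes$y[match(edges$to, nodes$disease)]
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$weight),
                   linetype = .data$weight < 0),
      colour = "grey55", show.legend = FALSE) +
      ggplot2::scale_linewidth(range = c(0.2, 1.6))
  }
  if (is.null(nodes$community)) {
    p <- p + ggplot2::geom_point(data = nodes,
                                 ggplot2::aes(.data$x, .data$y), size = 5,
                                 colour = "steelblue")
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$community), size = 5)
  }
  p + ggplot2::geom_text(data = nodes,
                         ggplot2::aes(.data$x, .data$y, label = .data$disease),
                         size = 2.4, vjust = -1.3) +
    ggplot2::theme_void()
}

#' @export
#' @method autoplot pairwise_network
autoplot.pairwise_network <- function(object, ...) plot_network(object, ...)

#' Plot centrality profiles
#'
#' Faceted dot plot of the six centrality metrics, diseases ordered by the
#' chosen metric.
#'
#' @param table A [compute_centralities()] tibble.
#' @param order_by Metric used to order diseases (default betweenness).
#' @return A ggplot object.
#' @export
plot_centrality <- function(table, order_by = "betweenness") {
  ord <- table$disease[order(table[[order_by]])]
  long <- tidyr::pivot_longer(table, -"disease", names_to = "metric",
                              values_to = "value")
  long$disease <- factor(long$disease, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$disease)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_x", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot prevalence by stratum
#'
#' Side-by-side bars of disease (or pattern) prevalence per stratum.
#'
#' @param prev A tibble from [summarize_prevalence()] or
#'   [pattern_prevalence()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prev) {
  item <- if ("disease" %in% names(prev)) "disease" else "pattern"
  value <- if ("proportion" %in% names(prev)) "proportion" else "prevalence"
  ggplot2::ggplot(prev, ggplot2::aes(.data[[item]], .data[[value]],
                                     fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "prevalence") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
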