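# Significance-thresholded brain networks.

#' Threshold a correlation matrix into a brain network
#'
#' Retains an undirected edge for every unordered ROI pair whose
#' correlation p-value is below `threshold_p` (default 0.05, a deliberate
#' sensitivity/specificity trade-off; no multiple-testing correction is
#' applied across the edge tests — pass a stricter `threshold_p` for
#' that). Edge weight is the signed Pearson r: negative edges are retained.
#' ROIs left without any retained edge are dropped from the node list.
#'
#' @param cm A [cor_matrix()] result.
#' @param threshold_p Significance level for edge retention (default 0.05).
#' @return A `brain_network`: tibble of edges (`from`, `to`, `weight`,
#'   `p`) with attributes `nodes` (retained, registry-ordered),
#'   `all_rois`, `threshold_p`, `group`, `n`.
#' @export
build_network <- function(cm, threshold_p = 0.05) {
  td <- tidy(cm)
  keep <- !is.na(td$p) & td$p < threshold_p
  edges <- td[keep, ]
  edges <- tibble(from = edges$roi1, to = edges$roi2,
                  weight = edges$r, p = edges$p)
  nodes <- cm$rois[cm$rois %in% c(edges$from, edges$to)]
  structure(edges,
            nodes = nodes, all_rois = cm$rois,
            threshold_p = threshold_p, group = cm$group, n = cm$n,
            class = c("brain_network", class(tibble())))
}

#' @rdname build_network
#' @param net A `brain_network`.
#' @export
network_nodes <- function(net) {
  attr(net, "nodes")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("Brain network%s: %d nodes, %d edges (p < %g)\n",
              if (!is.null(attr(x, "group")))
                paste0(" [", attr(x, "group"), "]") else "",
              length(attr(x, "nodes")), nrow(x), attr(x, "threshold_p")))
  invisible(x)
}

#' Convert a brain network to an igraph graph
#'
#' Retained (non-isolated) ROIs become vertices; `weight` (signed r) and
#' `p` are carried as edge attributes.
#'
#' @param net A [build_network()] result.
#' @param ... Unused.
#' @return An undirected [igraph::igraph] object.
#' @export
as_igraph <- function(net, ...) {
  igraph::graph_from_data_frame(
    as.data.frame(net[, c("from", "to", "weight", "p")]),
    directed = FALSE,
    vertices = data.frame(name = network_nodes(net))
  )
}

#' Export a network for external visualization
#'
#' Writes a Cytoscape-compatible weighted edge list (`source`, `target`,
#' `weight`, `p`) and a GraphML file.
#'
#' @param net A [build_network()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix (defaults to the group label).
#' @return Paths of the written files, invisibly.
#' @export
write_network <- function(net, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- prefix %||% .slug(attr(net, "group") %||% "network")
  edge_path <- file.path(dir, paste0("edges_", prefix, ".csv"))
  graphml_path <- file.path(dir, paste0("network_", prefix, ".graphml"))
  utils::write.csv(
    data.frame(source = net$from, target = net$to,
               weight = net$weight, p = net$p),
    edge_path, row.names = FALSE)
  igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = graphml_path))
}

#' @method tidy brain_network
#' @export
tidy.brain_network <- function(x, ...) {
  as_tibble(x)
}

#' @method autoplot brain_network
#' @export
autoplot.brain_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(roi = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  degree = igraph::degree(g))
  edges <- as_tibble(object) |>
    left_join(nodes |> select(from = "roi", x1 = "x", y1 = "y"),
              by = "from") |>
    left_join(nodes |> select(to = "roi", x2 = "x", y2 = "y"),
              by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, colour = .data$weight > 0,
                   linewidth = abs(.data$weight)),
      alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30",
                                            `FALSE` = "steelblue"),
                                 name = "positive r") +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     size = .data$degree),
                        colour = "firebrick3") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$roi),
                       vjust = -1, size = 3) +
    ggplot2::scale_size(range = c(1.5, 5), name = "degree") +
    ggplot2::labs(title = attr(object, "group")) +
    ggplot2::theme_void()
}
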