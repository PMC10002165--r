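# Global and per-node graph measures of the thresholded networks.
#
# Topology metrics (paths, clustering, components, centralities) treat the
# network as unweighted: every retained edge counts 1 regardless of the
# sign or magnitude of its correlation weight, since negative weights have
# no shortest-path semantics.

#' Network density (ordered-pair convention)
#'
#' `density = E / (N * (N - 1))`: the edge count over the number of
#' *ordered* node pairs. Note this convention — under it a complete
#' undirected graph has density 0.5, and it is the convention consistent
#' with the reference node/edge/density tables this package reproduces
#' (e.g. 128 edges on 32 nodes -> 128/992 = 0.129).
#'
#' @param n_nodes Number of retained nodes (>= 2).
#' @param n_edges Number of retained edges.
#' @return Density as a real number.
#' @examples
#' network_density(32, 128)  # 0.129...
#' @export
network_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) {
    abort("Density needs at least 2 nodes.",
          class = "iegnet_validation_error")
  }
  n_edges / (n_nodes * (n_nodes - 1))
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path length over all ordered pairs of distinct
#' nodes that are connected; pairs in different components are excluded
#' from the average (which keeps the value finite on fragmented networks).
#'
#' @param net A [build_network()] result with at least one edge.
#' @return Mean shortest-path length; `NA` (with a warning) for an
#'   edgeless network.
#' @export
characteristic_path_length <- function(net) {
  if (nrow(net) == 0) {
    warn("Characteristic path length is undefined for an edgeless network.")
    return(NA_real_)
  }
  igraph::mean_distance(as_igraph(net), weights = NA, directed = FALSE,
                        unconnected = TRUE)
}

#' Clustering coefficient
#'
#' `"local_average"` (default): mean of the local clustering coefficients
#' over retained nodes, where nodes of degree < 2 contribute 0.
#' `"transitivity"`: the global triangle/triplet ratio.
#'
#' @param net A [build_network()] result.
#' @param type `"local_average"` or `"transitivity"`.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(net,
                                   type = c("local_average", "transitivity")) {
  type <- match.arg(type)
  g <- as_igraph(net)
  if (type == "local_average") {
    local <- igraph::transitivity(g, type = "local", isolates = "zero")
    local[is.na(local)] <- 0  # degree-1 nodes
    mean(local)
  } else {
    t <- igraph::transitivity(g, type = "global")
    if (is.na(t)) 0 else t
  }
}

#' Connected components of a network
#'
#' Components are computed over the retained (non-isolated) nodes.
#'
#' @param net A [build_network()] result.
#' @return List with `n_components` and `membership`, a tibble (`roi`,
#'   `component`).
#' @export
connected_components <- function(net) {
  if (length(network_nodes(net)) == 0) {
    return(list(n_components = 0L,
                membership = tibble(roi = character(),
                                    component = integer())))
  }
  comp <- igraph::components(as_igraph(net))
  list(n_components = comp$no,
       membership = tibble(roi = names(comp$membership),
                           component = as.integer(comp$membership)))
}

#' Per-node degree and betweenness centrality
#'
#' Degree is the incident-edge count; betweenness is the sum over node
#' pairs of the fraction of (unweighted) shortest paths passing through
#' the node. Betweenness is unnormalized by default; the normalized
#' variant divides by `(N - 1) * (N - 2) / 2`.
#'
#' @param net A [build_network()] result.
#' @param normalized Normalize betweenness (default FALSE).
#' @return Tibble (`roi`, `degree`, `betweenness`), one row per retained
#'   node in registry order.
#' @export
node_centralities <- function(net, normalized = FALSE) {
  nodes <- network_nodes(net)
  if (length(nodes) == 0) {
    return(tibble(roi = character(), degree = integer(),
                  betweenness = double()))
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = normalized)
  tibble(roi = nodes, degree = as.integer(deg[nodes]),
         betweenness = as.numeric(btw[nodes]))
}

#' Global strength of a correlation matrix
#'
#' The sum of absolute Pearson correlations over all unordered ROI pairs.
#' By default it is taken over the *full* (unthresholded) matrix — the
#' whole-network statistic used by the permutation comparison; setting
#' `thresholded = TRUE` restricts the sum to retained edges of a network
#' built at `threshold_p`.
#'
#' @param cm A [cor_matrix()] result.
#' @param thresholded Sum only over significant edges (default FALSE).
#' @param threshold_p Edge-retention level when `thresholded = TRUE`.
#' @return Non-negative real number.
#' @export
global_strength <- function(cm, thresholded = FALSE, threshold_p = 0.05) {
  if (length(cm$constant_rois) || anyNA(cm$r)) {
    abort("Correlation matrix has undefined entries.",
          class = "iegnet_validation_error")
  }
  if (thresholded) {
    net <- build_network(cm, threshold_p)
    sum(abs(net$weight))
  } else {
    sum(abs(cm$r[upper.tri(cm$r)]))
  }
}

#' Summary metrics of a brain network
#'
#' The whole-network descriptor set: node and edge counts, density
#' (ordered-pair convention), characteristic path length, connected
#' components and mean local clustering coefficient; plus global strength
#' of the source correlation matrix when it is supplied.
#'
#' @param net A [build_network()] result.
#' @param cm Optional [cor_matrix()] the network came from; adds
#'   `global_strength`.
#' @return One-row tibble.
#' @export
network_metrics <- function(net, cm = NULL) {
  n_nodes <- length(network_nodes(net))
  n_edges <- nrow(net)
  tibble(
    group = attr(net, "group") %||% NA_character_,
    n_nodes = n_nodes,
    n_edges = n_edges,
    density = if (n_nodes >= 2) network_density(n_nodes, n_edges)
              else NA_real_,
    characteristic_path_length =
      if (n_edges > 0) characteristic_path_length(net) else NA_real_,
    n_components = connected_components(net)$n_components,
    clustering_coefficient =
      if (n_nodes > 0) clustering_coefficient(net) else NA_real_,
    global_strength = if (!is.null(cm)) global_strength(cm) else NA_real_
  )
}

#' @method glance brain_network
#' @export
glance.brain_network <- function(x, ...) {
  network_metrics(x)
}
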