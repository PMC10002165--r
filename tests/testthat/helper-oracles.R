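# Independent brute-force oracles used to validate the graph and
# correlation machinery. These deliberately avoid igraph and stats::cor:
# textbook formulas, min-plus matrix products, exhaustive simple-path
# enumeration and union-find.

# Pearson r by the raw product-moment sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# All-pairs unweighted shortest paths by repeated min-plus products.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (rep in seq_len(n)) {
    d_new <- d
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d_new[i, j] <- min(d[i, ] + d[, j])
      }
    }
    if (identical(d_new, d)) break
    d <- d_new
  }
  d
}

# All simple paths from s to t (vectors of vertices), by DFS.
.all_simple_paths <- function(adj, s, t) {
  paths <- list()
  walk_on <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% path)) walk_on(c(path, w))
    }
  }
  walk_on(s)
  paths
}

# Unnormalized betweenness by exhaustive shortest-path enumeration:
# for every unordered pair (s, t), the fraction of shortest simple paths
# through each interior vertex.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- .all_simple_paths(adj, s, t)
      if (!length(paths)) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  btw
}

# Mean local clustering, degree < 2 contributing 0.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  local <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))
  mean(local)
}

# Connected components by union-find.
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Random symmetric adjacency matrix (no self-loops).
random_adjacency <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# Wrap an adjacency matrix as a brain_network (unit-ish weights) so the
# metric functions can be exercised on arbitrary graphs.
network_from_adjacency <- function(adj, rois = NULL) {
  n <- nrow(adj)
  rois <- rois %||% paste0("R", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(from = rois[idx[, 1]], to = rois[idx[, 2]],
                          weight = 0.9, p = 0.01)
  nodes <- rois[rois %in% c(edges$from, edges$to)]
  structure(edges, nodes = nodes, all_rois = rois, threshold_p = 0.05,
            group = NULL, n = NA_integer_,
            class = c("brain_network", class(tibble::tibble())))
}

`%||%` <- rlang::`%||%`
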