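# Permutation machinery: animal-label reassignment between two groups,
# exhaustive when feasible, Monte-Carlo otherwise.

#' Generate pseudo-group label assignments
#'
#' Pools the `n_a + n_b` animals of two groups and reassigns them to
#' pseudo-groups of the original sizes. Whole animals are the exchangeable
#' unit. When the number of distinct assignments `C(n_a + n_b, n_a)` does
#' not exceed `B`, all of them are enumerated exactly once (exhaustive
#' mode, which includes the observed assignment and is strictly better
#' than sampling); otherwise `B` uniform random assignments are drawn.
#' For the canonical 5 + 5 design, `C(10, 5) = 252 < 1000`, so the default
#' budget triggers exhaustive mode.
#'
#' @param n_a,n_b Group sizes (each >= 3).
#' @param B Permutation budget (default 1000).
#' @param seed Integer seed; required in Monte-Carlo mode.
#' @param force_monte_carlo Always sample `B` random assignments, even
#'   when exhaustive enumeration is feasible.
#' @return List with `assignments` (integer matrix, one row per
#'   assignment: the pooled indices, `1..n_a` first group, forming the
#'   pseudo-A set), `exhaustive` (flag) and `B` (rows).
#' @export
permute_labels <- function(n_a, n_b, B = 1000, seed = NULL,
                           force_monte_carlo = FALSE) {
  if (n_a < 3 || n_b < 3) {
    abort("Both groups need at least 3 animals for a permutation test.",
          class = "iegnet_validation_error")
  }
  n <- n_a + n_b
  n_total <- choose(n, n_a)
  exhaustive <- (n_total <= B) && !force_monte_carlo
  if (exhaustive) {
    assignments <- t(utils::combn(n, n_a))
  } else {
    if (is.null(seed)) {
      abort("Monte-Carlo permutation sampling requires a seed.",
            class = "iegnet_validation_error")
    }
    set.seed(seed)
    assignments <- t(vapply(seq_len(B),
                            function(i) sort(sample.int(n, n_a)),
                            integer(n_a)))
  }
  list(assignments = assignments, exhaustive = exhaustive,
       B = nrow(assignments), seed = seed)
}

# Correlation matrix that never propagates NA: pairs involving a column
# made constant by a permutation get r = 0 (recorded in `counter`), which
# keeps the null distribution complete instead of dropping assignments.
.safe_cor <- function(m, counter = NULL) {
  r <- suppressWarnings(stats::cor(m))
  nas <- which(is.na(r))
  if (length(nas)) {
    if (!is.null(counter)) {
      counter$flags <- counter$flags + length(nas) / 2
    }
    r[nas] <- 0
  }
  diag(r) <- 1
  r
}

# Shared permutation engine. `stat_fun(m1, m2)` maps two animals-by-ROIs
# matrices to a named statistic vector; the observed value uses the
# original grouping, the null re-splits the pooled animals per assignment.
# Two-sided p on absolute values; exhaustive mode reports the plain null
# proportion (the identity assignment is one of the enumerated ones, so
# p > 0), Monte-Carlo mode uses the add-one estimator (x + 1) / (B + 1).
.perm_test <- function(m_a, m_b, stat_fun, B = 1000, seed = NULL,
                       force_monte_carlo = FALSE, perms = NULL) {
  n_a <- nrow(m_a); n_b <- nrow(m_b)
  pooled <- rbind(m_a, m_b)
  perms <- perms %||% permute_labels(n_a, n_b, B = B, seed = seed,
                                     force_monte_carlo = force_monte_carlo)
  observed <- stat_fun(m_a, m_b)
  null_values <- t(apply(perms$assignments, 1, function(idx) {
    stat_fun(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])
  }))
  if (length(observed) == 1) null_values <- t(null_values)
  hits <- sweep(abs(null_values), 2, abs(observed) - 1e-12, `>=`)
  p <- if (perms$exhaustive) {
    colMeans(hits)
  } else {
    (colSums(hits) + 1) / (perms$B + 1)
  }
  list(observed = observed, p = unname(p), null_values = null_values,
       exhaustive = perms$exhaustive, B = perms$B, seed = perms$seed)
}

.perm_attrs <- function(x, res, statistic, alpha, extra = list()) {
  attrs <- c(list(statistic = statistic, B = res$B,
                  exhaustive = res$exhaustive, seed = res$seed,
                  alpha = alpha, null_values = res$null_values),
             extra)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c("ieg_perm_test", class(tibble()))
  x
}

# Statistic builders -------------------------------------------------------

.stat_edge_diff <- function(rois, counter) {
  ut <- upper.tri(diag(length(rois)))
  function(m1, m2) {
    .safe_cor(m1, counter)[ut] - .safe_cor(m2, counter)[ut]
  }
}

.stat_strength_diff <- function(counter) {
  function(m1, m2) {
    r1 <- .safe_cor(m1, counter); r2 <- .safe_cor(m2, counter)
    sum(abs(r1[upper.tri(r1)])) - sum(abs(r2[upper.tri(r2)]))
  }
}

# Per-node metric over *all* ROIs of the thresholded pseudo-network;
# isolated nodes carry 0.
.node_metric <- function(m, metric, threshold_p, counter) {
  r <- .safe_cor(m, counter)
  n <- nrow(m)
  p <- matrix(pearson_p(r, n), nrow(r), ncol(r))
  adj <- (p < threshold_p) & !is.na(p)
  diag(adj) <- FALSE
  if (metric == "degree") {
    colSums(adj)
  } else {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    as.numeric(igraph::betweenness(g, directed = FALSE))
  }
}

.stat_centrality_diff <- function(metric, threshold_p, counter) {
  function(m1, m2) {
    .node_metric(m1, metric, threshold_p, counter) -
      .node_metric(m2, metric, threshold_p, counter)
  }
}

# Public tests --------------------------------------------------------------

#' Edge-wise permutation test of correlation differences
#'
#' For every unordered ROI pair, the observed statistic is
#' `r_A - r_B`; the null redistributes the pooled animals into
#' pseudo-groups and recomputes both correlation matrices per assignment.
#' Following the thresholding convention of the network stage, no
#' multiple-testing correction is applied across the pairs.
#'
#' @param study An [ieg_study()].
#' @param group_a,group_b Group labels; differences are `A - B`.
#' @param B Permutation budget (default 1000; see [permute_labels()]).
#' @param seed Seed for Monte-Carlo mode.
#' @param alpha Significance level for the `significant` flag (0.05).
#' @param threshold_p Unused here; present for interface symmetry.
#' @param force_monte_carlo See [permute_labels()].
#' @return An `ieg_perm_test` tibble: `roi1`, `roi2`, `observed`, `p`,
#'   `significant`; attributes carry the statistic name, permutation
#'   counts, exhaustive flag, seed and constant-column flag count.
#' @export
edge_difference_test <- function(study, group_a, group_b, B = 1000,
                                 seed = NULL, alpha = 0.05,
                                 force_monte_carlo = FALSE) {
  m_a <- expression_table(study, group_a)
  m_b <- expression_table(study, group_b)
  rois <- colnames(m_a)
  counter <- new.env(); counter$flags <- 0
  res <- .perm_test(m_a, m_b, .stat_edge_diff(rois, counter), B = B,
                    seed = seed, force_monte_carlo = force_monte_carlo)
  idx <- which(upper.tri(diag(length(rois))), arr.ind = TRUE)
  out <- tibble(roi1 = rois[idx[, 1]], roi2 = rois[idx[, 2]],
                observed = unname(res$observed), p = res$p,
                significant = res$p < alpha)
  .perm_attrs(out, res, "edge_r_diff", alpha,
              list(groups = c(group_a, group_b),
                   n_constant_flags = counter$flags))
}

#' Permutation test of the global strength difference
#'
#' Global strength is the sum of `|r|` over all unordered ROI pairs of the
#' full (unthresholded) correlation matrix; the observed statistic is
#' `S_A - S_B`.
#'
#' @inheritParams edge_difference_test
#' @return One-row `ieg_perm_test` tibble: `observed`, `p`,
#'   `significant`; the null values are kept in the `null_values`
#'   attribute.
#' @export
global_strength_test <- function(study, group_a, group_b, B = 1000,
                                 seed = NULL, alpha = 0.05,
                                 force_monte_carlo = FALSE) {
  m_a <- expression_table(study, group_a)
  m_b <- expression_table(study, group_b)
  counter <- new.env(); counter$flags <- 0
  res <- .perm_test(m_a, m_b, .stat_strength_diff(counter), B = B,
                    seed = seed, force_monte_carlo = force_monte_carlo)
  out <- tibble(observed = unname(res$observed), p = res$p,
                significant = res$p < alpha)
  .perm_attrs(out, res, "global_strength_diff", alpha,
              list(groups = c(group_a, group_b),
                   n_constant_flags = counter$flags))
}

#' Per-node permutation test of centrality differences
#'
#' For each permuted assignment both pseudo-group matrices are thresholded
#' into networks (p < `threshold_p`) and the chosen centrality recomputed
#' over all registry ROIs; a node isolated in a network carries metric 0.
#' The observed statistic per node is `metric_A - metric_B`.
#'
#' @inheritParams edge_difference_test
#' @param metric `"degree"` or `"betweenness"` (unnormalized).
#' @param threshold_p Edge-retention level of the pseudo-networks (0.05).
#' @return An `ieg_perm_test` tibble with one row per ROI: `roi`,
#'   `observed`, `p`, `significant`.
#' @export
centrality_test <- function(study, group_a, group_b,
                            metric = c("degree", "betweenness"),
                            threshold_p = 0.05, B = 1000, seed = NULL,
                            alpha = 0.05, force_monte_carlo = FALSE) {
  metric <- match.arg(metric)
  m_a <- expression_table(study, group_a)
  m_b <- expression_table(study, group_b)
  rois <- colnames(m_a)
  counter <- new.env(); counter$flags <- 0
  res <- .perm_test(m_a, m_b,
                    .stat_centrality_diff(metric, threshold_p, counter),
                    B = B, seed = seed,
                    force_monte_carlo = force_monte_carlo)
  out <- tibble(roi = rois, observed = unname(res$observed), p = res$p,
                significant = res$p < alpha)
  .perm_attrs(out, res, paste0(metric, "_diff"), alpha,
              list(groups = c(group_a, group_b),
                   threshold_p = threshold_p,
                   n_constant_flags = counter$flags))
}

#' @method tidy ieg_perm_test
#' @export
tidy.ieg_perm_test <- function(x, ...) {
  as_tibble(x)
}

#' @method glance ieg_perm_test
#' @export
glance.ieg_perm_test <- function(x, ...) {
  tibble(statistic = attr(x, "statistic"),
         group_a = attr(x, "groups")[1], group_b = attr(x, "groups")[2],
         B = attr(x, "B"), exhaustive = attr(x, "exhaustive"),
         alpha = attr(x, "alpha"),
         n_units = nrow(x), n_significant = sum(x$significant))
}
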