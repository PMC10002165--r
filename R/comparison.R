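# Assembled two-group network comparison: edge-wise, global strength and
# per-node centrality permutation tests sharing one assignment set.

#' Full permutation comparison of two treatment groups
#'
#' Runs the edge-wise correlation-difference test, the global-strength
#' test and the per-node degree and betweenness tests between two groups,
#' all on a single shared set of label assignments (exhaustive when
#' feasible, see [permute_labels()]).
#'
#' @inheritParams centrality_test
#' @return An `ieg_comparison` list: `groups`, `edges`,
#'   `global_strength`, `degree`, `betweenness` (each an
#'   `ieg_perm_test`), plus `alpha`, `threshold_p`, `B`, `exhaustive`,
#'   `seed`.
#' @export
compare_groups <- function(study, group_a, group_b, threshold_p = 0.05,
                           alpha = 0.05, B = 1000, seed = NULL,
                           force_monte_carlo = FALSE) {
  m_a <- expression_table(study, group_a)
  m_b <- expression_table(study, group_b)
  rois <- colnames(m_a)
  k <- length(rois)
  n_pairs <- k * (k - 1) / 2
  counter <- new.env(); counter$flags <- 0

  perms <- permute_labels(nrow(m_a), nrow(m_b), B = B, seed = seed,
                          force_monte_carlo = force_monte_carlo)

  edge_stat <- .stat_edge_diff(rois, counter)
  deg_stat <- .stat_centrality_diff("degree", threshold_p, counter)
  btw_stat <- .stat_centrality_diff("betweenness", threshold_p, counter)
  ut <- upper.tri(diag(k))
  combined <- function(m1, m2) {
    r1 <- .safe_cor(m1, counter); r2 <- .safe_cor(m2, counter)
    c(r1[ut] - r2[ut],
      sum(abs(r1[ut])) - sum(abs(r2[ut])),
      deg_stat(m1, m2),
      btw_stat(m1, m2))
  }
  res <- .perm_test(m_a, m_b, combined, B = B, seed = seed,
                    force_monte_carlo = force_monte_carlo, perms = perms)

  slice_res <- function(cols) {
    list(observed = res$observed[cols], p = res$p[cols],
         null_values = res$null_values[, cols, drop = FALSE],
         exhaustive = res$exhaustive, B = res$B, seed = res$seed)
  }
  idx <- which(ut, arr.ind = TRUE)
  grp <- c(group_a, group_b)

  edges <- tibble(roi1 = rois[idx[, 1]], roi2 = rois[idx[, 2]],
                  observed = unname(res$observed[seq_len(n_pairs)]),
                  p = res$p[seq_len(n_pairs)])
  edges$significant <- edges$p < alpha
  edges <- .perm_attrs(edges, slice_res(seq_len(n_pairs)), "edge_r_diff",
                       alpha, list(groups = grp))

  gs_cols <- n_pairs + 1
  gs <- tibble(observed = unname(res$observed[gs_cols]), p = res$p[gs_cols])
  gs$significant <- gs$p < alpha
  gs <- .perm_attrs(gs, slice_res(gs_cols), "global_strength_diff", alpha,
                    list(groups = grp))

  node_block <- function(offset, name) {
    cols <- n_pairs + 1 + offset + seq_len(k)
    out <- tibble(roi = rois, observed = unname(res$observed[cols]),
                  p = res$p[cols])
    out$significant <- out$p < alpha
    .perm_attrs(out, slice_res(cols), name, alpha,
                list(groups = grp, threshold_p = threshold_p))
  }

  structure(list(groups = grp,
                 edges = edges,
                 global_strength = gs,
                 degree = node_block(0, "degree_diff"),
                 betweenness = node_block(k, "betweenness_diff"),
                 alpha = alpha, threshold_p = threshold_p,
                 B = res$B, exhaustive = res$exhaustive, seed = res$seed,
                 n_constant_flags = counter$flags),
            class = "ieg_comparison")
}

#' @export
print.ieg_comparison <- function(x, ...) {
  cat(sprintf("Network comparison %s vs %s (%s, B = %d)\n",
              x$groups[1], x$groups[2],
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$B))
  cat(sprintf("  significant edges: %d / %d\n",
              sum(x$edges$significant), nrow(x$edges)))
  cat(sprintf("  global strength diff: %.3f (p = %.3f)\n",
              x$global_strength$observed, x$global_strength$p))
  cat(sprintf("  significant degree nodes: %d, betweenness nodes: %d\n",
              sum(x$degree$significant), sum(x$betweenness$significant)))
  invisible(x)
}

#' Signed-difference matrix of significant edge differences
#'
#' Square ROI-by-ROI matrix holding `sign(r_A - r_B)` where the edge-wise
#' permutation test is significant and 0 elsewhere — the matrix-display
#' analogue of the comparison figures.
#'
#' @param comparison An [compare_groups()] result.
#' @return Integer matrix in `{-1, 0, 1}` with zero diagonal.
#' @export
signed_differences <- function(comparison) {
  e <- comparison$edges
  rois <- unique(c(e$roi1, e$roi2))
  m <- matrix(0L, length(rois), length(rois),
              dimnames = list(rois, rois))
  sig <- e[e$significant, ]
  if (nrow(sig)) {
    s <- as.integer(sign(sig$observed))
    m[cbind(match(sig$roi1, rois), match(sig$roi2, rois))] <- s
    m[cbind(match(sig$roi2, rois), match(sig$roi1, rois))] <- s
  }
  m
}

#' @method tidy ieg_comparison
#' @export
tidy.ieg_comparison <- function(x, ...) {
  bind_rows(
    x$edges |> as_tibble() |>
      mutate(unit = paste(.data$roi1, .data$roi2, sep = "-"),
             statistic = "edge_r_diff") |>
      select("statistic", "unit", "observed", "p", "significant"),
    x$global_strength |> as_tibble() |>
      mutate(unit = "network", statistic = "global_strength_diff") |>
      select("statistic", "unit", "observed", "p", "significant"),
    x$degree |> as_tibble() |>
      mutate(unit = .data$roi, statistic = "degree_diff") |>
      select("statistic", "unit", "observed", "p", "significant"),
    x$betweenness |> as_tibble() |>
      mutate(unit = .data$roi, statistic = "betweenness_diff") |>
      select("statistic", "unit", "observed", "p", "significant")
  )
}

#' @method glance ieg_comparison
#' @export
glance.ieg_comparison <- function(x, ...) {
  tibble(group_a = x$groups[1], group_b = x$groups[2],
         B = x$B, exhaustive = x$exhaustive, alpha = x$alpha,
         n_significant_edges = sum(x$edges$significant),
         global_strength_diff = x$global_strength$observed,
         global_strength_p = x$global_strength$p,
         n_significant_degree = sum(x$degree$significant),
         n_significant_betweenness = sum(x$betweenness$significant))
}

#' Write the comparison report files
#'
#' A CSV of significant signed edge differences, a CSV of the per-node
#' tests, and a JSON summary.
#'
#' @param comparison An [compare_groups()] result.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_comparison_report <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slug <- paste(.slug(comparison$groups[1]), "vs",
                .slug(comparison$groups[2]), sep = "_")
  edge_path <- file.path(dir, paste0("edge_diff_", slug, ".csv"))
  node_path <- file.path(dir, paste0("node_diff_", slug, ".csv"))
  json_path <- file.path(dir, paste0("comparison_", slug, ".json"))

  sig <- comparison$edges |> filter(.data$significant) |>
    mutate(sign = sign(.data$observed))
  utils::write.csv(as.data.frame(sig), edge_path, row.names = FALSE)

  nodes <- bind_rows(
    comparison$degree |> as_tibble() |> mutate(metric = "degree"),
    comparison$betweenness |> as_tibble() |>
      mutate(metric = "betweenness")
  )
  utils::write.csv(as.data.frame(nodes), node_path, row.names = FALSE)

  jsonlite::write_json(
    as.list(glance(comparison)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(edges = edge_path, nodes = node_path, summary = json_path))
}

#' @method autoplot ieg_comparison
#' @export
autoplot.ieg_comparison <- function(object, ...) {
  m <- signed_differences(object)
  rois <- rownames(m)
  df <- tibble(roi1 = rep(rois, times = length(rois)),
               roi2 = rep(rois, each = length(rois)),
               sign = as.vector(m))
  df$roi1 <- factor(df$roi1, levels = rois)
  df$roi2 <- factor(df$roi2, levels = rev(rois))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi1, .data$roi2,
                                   fill = factor(.data$sign))) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_manual(
      values = c(`-1` = "steelblue4", `0` = "white", `1` = "firebrick3"),
      name = "sign of\nsignificant diff") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s vs %s", object$groups[1],
                                  object$groups[2])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
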