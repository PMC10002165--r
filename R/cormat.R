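# Group-wise Pearson correlation matrices with exact t-based p-values.

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact transform `t = r * sqrt((n - 2) / (1 - r^2))` referred to
#' the t distribution with `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value(s); 0 when `|r| = 1`.
#' @examples
#' pearson_p(0.8, 5)  # ~0.104
#' @export
pearson_p <- function(r, n) {
  if (n < 3) {
    abort("Pearson p-value needs n >= 3 (df = n - 2 >= 1).",
          class = "iegnet_validation_error")
  }
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  t_stat <- ifelse(abs(r[ok]) < 1,
                   r[ok] * sqrt((n - 2) / (1 - r[ok]^2)),
                   Inf * sign(r[ok]))
  p[ok] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p
}

#' Pairwise Pearson correlation matrix of one group
#'
#' Computes all pairwise correlations between registry ROIs across the
#' animals of one treatment group, with two-sided p-values from the exact
#' t transform at `n - 2` degrees of freedom. ROIs with zero variance
#' (constant columns) get `NA` correlations with every partner and are
#' flagged; downstream network construction skips them.
#'
#' @param x An [ieg_study()] (give `group`) or a numeric animals-by-ROIs
#'   matrix.
#' @param group Group label (required for a study input).
#' @return A `roi_cormat`: list with `rois`, `r` (symmetric, unit
#'   diagonal), `p` (symmetric, `NA` diagonal), `n` (animals),
#'   `constant_rois`, `group`.
#' @export
cor_matrix <- function(x, group = NULL) {
  if (inherits(x, "ieg_study")) {
    if (is.null(group)) {
      abort("Give `group` when `x` is a study.",
            class = "iegnet_validation_error")
    }
    m <- expression_table(x, group)
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) {
      colnames(m) <- paste0("V", seq_len(ncol(m)))
    }
  }
  n <- nrow(m)
  if (n < 3) {
    abort("At least 3 animals are needed for correlation p-values.",
          class = "iegnet_validation_error")
  }
  sds <- apply(m, 2, stats::sd)
  constant <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  if (length(constant)) {
    warn(paste0("Constant ROI column(s), correlations undefined: ",
                paste(constant, collapse = ", ")))
  }
  over <- which(abs(r) > 1)  # guard fp overshoot
  r[over] <- sign(r[over])
  p <- matrix(pearson_p(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
  diag(p) <- NA_real_
  diag(r) <- 1

  structure(list(rois = colnames(m), r = r, p = p, n = n,
                 constant_rois = constant, group = group),
            class = "roi_cormat")
}

#' @export
print.roi_cormat <- function(x, ...) {
  cat(sprintf("Pearson correlation matrix: %d ROIs, n = %d%s\n",
              length(x$rois), x$n,
              if (!is.null(x$group)) paste0(" (group ", x$group, ")") else ""))
  invisible(x)
}

#' @method tidy roi_cormat
#' @export
tidy.roi_cormat <- function(x, ...) {
  k <- length(x$rois)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(roi1 = x$rois[idx[, 1]], roi2 = x$rois[idx[, 2]],
         r = x$r[idx], p = x$p[idx])
}

#' @method glance roi_cormat
#' @export
glance.roi_cormat <- function(x, ...) {
  td <- tidy(x)
  tibble(group = x$group %||% NA_character_, n = x$n,
         n_pairs = nrow(td),
         n_significant = sum(td$p < 0.05, na.rm = TRUE),
         global_strength = sum(abs(td$r), na.rm = TRUE))
}

#' Hierarchical-clustering display order of a correlation matrix
#'
#' Agglomerative clustering (average linkage) on the dissimilarity
#' `1 - r`; the dendrogram leaf order groups strongly correlated ROIs for
#' matrix display. The linkage choice is recorded on the result.
#'
#' @param cm A [cor_matrix()] result without undefined entries.
#' @return Character vector: a permutation of the ROIs.
#' @export
hierarchical_order <- function(cm) {
  if (length(cm$constant_rois) || anyNA(cm$r)) {
    abort("Correlation matrix has undefined entries; drop the affected ROI(s) first.",
          class = "iegnet_validation_error")
  }
  hc <- stats::hclust(stats::as.dist(1 - cm$r), method = "average")
  structure(cm$rois[hc$order], linkage = "average")
}

#' Write the r and p matrices of a group as square CSV files
#'
#' @param cm A [cor_matrix()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix (defaults to the group label).
#' @return Paths of the two files, invisibly.
#' @export
write_cor_matrix <- function(cm, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- prefix %||% .slug(cm$group %||% "group")
  paths <- c(
    r = file.path(dir, paste0("cor_r_", prefix, ".csv")),
    p = file.path(dir, paste0("cor_p_", prefix, ".csv"))
  )
  utils::write.csv(as.data.frame(cm$r), paths["r"])
  utils::write.csv(as.data.frame(cm$p), paths["p"])
  invisible(paths)
}

#' @method autoplot roi_cormat
#' @export
autoplot.roi_cormat <- function(object, order = c("clustered", "registry"),
                                ...) {
  order <- match.arg(order)
  lev <- if (order == "clustered" && !length(object$constant_rois)) {
    hierarchical_order(object)
  } else {
    object$rois
  }
  df <- tidy(object)
  df2 <- tibble(roi1 = c(df$roi1, df$roi2, object$rois),
                roi2 = c(df$roi2, df$roi1, object$rois),
                r = c(df$r, df$r, rep(1, length(object$rois))))
  df2$roi1 <- factor(df2$roi1, levels = lev)
  df2$roi2 <- factor(df2$roi2, levels = rev(lev))
  ggplot2::ggplot(df2, ggplot2::aes(.data$roi1, .data$roi2,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = object$group) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
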