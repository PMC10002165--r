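test_that("pearson matrix matches hand-computed and reference values", {
  m <- cbind(x = c(1, 2, 3, 4, 5), y = c(1, 3, 2, 5, 4))
  cm <- cor_matrix(m)
  expect_equal(cm$r["x", "y"], 0.8)
  ref <- cor.test(m[, 1], m[, 2])
  expect_equal(cm$p["x", "y"], ref$p.value, tolerance = 1e-12)
  expect_equal(cm$p["x", "y"], 0.104, tolerance = 1e-3)
  expect_equal(cm$n, 5)

  dup <- cbind(a = c(1, 5, 3, 2), b = c(1, 5, 3, 2))
  cm2 <- cor_matrix(dup)
  expect_equal(cm2$r["a", "b"], 1)
  expect_equal(cm2$p["a", "b"], 0)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(12)
  for (i in 1:10) {
    k <- sample(3:8, 1); n <- sample(4:9, 1)
    m <- matrix(rnorm(n * k), n, k)
    cm <- cor_matrix(m)
    expect_equal(cm$r, t(cm$r))
    expect_equal(unname(diag(cm$r)), rep(1, k))
    expect_true(all(abs(cm$r) <= 1))
    expect_equal(cm$p, t(cm$p))
    off <- cm$p[upper.tri(cm$p)]
    expect_true(all(off >= 0 & off <= 1))
  }
})

test_that("pearson r agrees with the double-loop oracle to 1e-12", {
  set.seed(77)
  for (i in 1:10) {
    k <- sample(3:6, 1); n <- sample(5:10, 1)
    m <- matrix(rnorm(n * k), n, k)
    cm <- cor_matrix(m)
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        expect_equal(cm$r[a, b], oracle_pearson(m[, a], m[, b]),
                     tolerance = 1e-12)
        expect_equal(cm$p[a, b], cor.test(m[, a], m[, b])$p.value,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("p decreases strictly with |r| at fixed n", {
  r_grid <- seq(0.05, 0.95, by = 0.05)
  for (n in c(5, 10, 20)) {
    p <- pearson_p(r_grid, n)
    expect_true(all(diff(p) < 0))
    expect_equal(pearson_p(-r_grid, n), p)  # two-sided symmetry
  }
})

test_that("constant columns are flagged and excluded from edges", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(2, 1, 4, 3, 5))
  expect_warning(cm <- cor_matrix(m), "Constant")
  expect_equal(cm$constant_rois, "b")
  expect_true(all(is.na(cm$r["b", c("a", "c")])))
  net <- build_network(cm, threshold_p = 1)
  expect_false("b" %in% c(net$from, net$to))
  expect_error(hierarchical_order(cm), class = "iegnet_validation_error")
  expect_error(global_strength(cm), class = "iegnet_validation_error")
})

test_that("network construction keeps only sub-threshold pairs", {
  set.seed(5)
  k <- 6; n <- 8
  m <- matrix(rnorm(n * k), n, k)
  cm <- cor_matrix(m)
  net <- build_network(cm, threshold_p = 0.05)
  if (nrow(net) > 0) {
    expect_true(all(net$p < 0.05))
    expect_true(all(abs(net$weight) <= 1))
    expect_true(all(net$from != net$to))
  }
  # all pairs at threshold 1, none at threshold 0
  expect_equal(nrow(build_network(cm, 1)), k * (k - 1) / 2)
  expect_equal(nrow(build_network(cm, 0)), 0)
  expect_length(network_nodes(build_network(cm, 0)), 0)

  # monotonicity: lowering the threshold never adds edges
  thresholds <- c(1, 0.5, 0.2, 0.1, 0.05, 0.01, 0.001)
  counts <- vapply(thresholds,
                   function(th) nrow(build_network(cm, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicated columns give the complete 528-edge graph", {
  set.seed(9)
  base <- rnorm(5)
  m <- matrix(rep(base, 33), nrow = 5,
              dimnames = list(NULL, registry_rois(roi_registry())))
  cm <- cor_matrix(m)
  net <- build_network(cm)
  expect_equal(nrow(net), 33 * 32 / 2)
  expect_equal(nrow(net), 528)
  expect_length(network_nodes(net), 33)
})

test_that("false-edge rate on null data matches the threshold", {
  reg <- small_registry(33)
  set.seed(202)
  edge_counts <- replicate(60, {
    m <- matrix(rnorm(5 * 33), 5, 33,
                dimnames = list(NULL, registry_rois(reg)))
    nrow(build_network(cor_matrix(m), 0.05))
  })
  expect_lt(abs(mean(edge_counts) / 528 - 0.05), 0.015)
})

test_that("hierarchical ordering clusters correlated ROIs together", {
  # three variables: 1 and 2 tightly correlated, 3 independent
  R <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cm <- list(rois = c("A", "B", "C"), r = R,
             p = matrix(0.5, 3, 3), n = 5, constant_rois = character(),
             group = NULL)
  class(cm) <- "roi_cormat"
  ord <- hierarchical_order(cm)
  expect_setequal(ord, c("A", "B", "C"))
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)  # adjacent leaves
  expect_identical(as.character(hierarchical_order(cm)),
                   as.character(ord))  # deterministic
})

test_that("matrix and network writers produce readable files", {
  tpl <- study_template("null", registry = small_registry(4), n_animals = 5)
  study <- generate_study(tpl, seed = 2)$study
  cm <- cor_matrix(study, "VEH/VEH")
  dir <- withr::local_tempdir()
  paths <- write_cor_matrix(cm, dir)
  r_back <- as.matrix(read.csv(paths["r"], row.names = 1))
  expect_equal(unname(r_back), unname(cm$r), tolerance = 1e-12)
  net <- build_network(cm, threshold_p = 0.5)
  npaths <- write_network(net, dir)
  edges <- read.csv(npaths["edges"])
  expect_named(edges, c("source", "target", "weight", "p"))
  expect_equal(nrow(edges), nrow(net))
  g <- igraph::read_graph(npaths["graphml"], format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net))
})
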