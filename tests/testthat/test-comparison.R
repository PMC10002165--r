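two_group_study <- function(n = 5, k = 4, seed = 1, shift_fun = NULL) {
  reg <- small_registry(k)
  set.seed(seed)
  mA <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, registry_rois(reg)))
  mB <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, registry_rois(reg)))
  if (!is.null(shift_fun)) mB <- shift_fun(mB)
  study_from_matrices(list(A = mA, B = mB), reg)
}

test_that("label permutation enumerates exhaustively when feasible", {
  p33 <- permute_labels(3, 3)
  expect_true(p33$exhaustive)
  expect_equal(p33$B, 20)           # C(6, 3)
  expect_equal(nrow(unique(p33$assignments)), 20)
  expect_equal(p33$assignments[1, ], 1:3)  # identity included

  p55 <- permute_labels(5, 5, B = 1000)
  expect_true(p55$exhaustive)       # C(10, 5) = 252 < 1000
  expect_equal(p55$B, 252)

  mc <- permute_labels(10, 10, B = 500, seed = 3)
  expect_false(mc$exhaustive)
  expect_equal(mc$B, 500)
  mc2 <- permute_labels(10, 10, B = 500, seed = 3)
  expect_identical(mc$assignments, mc2$assignments)
  expect_error(permute_labels(2, 5), class = "iegnet_validation_error")
  expect_error(permute_labels(10, 10, B = 100),
               class = "iegnet_validation_error")  # MC without seed

  forced <- permute_labels(5, 5, B = 100, seed = 1,
                           force_monte_carlo = TRUE)
  expect_false(forced$exhaustive)
  expect_equal(forced$B, 100)
})

test_that("identical groups give zero observed differences and p = 1", {
  reg <- small_registry(3)
  set.seed(2)
  m <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, registry_rois(reg)))
  study <- study_from_matrices(list(A = m, B = m), reg)
  ed <- edge_difference_test(study, "A", "B")
  expect_true(all(ed$observed == 0))
  expect_true(all(ed$p == 1))
  gs <- global_strength_test(study, "A", "B")
  expect_equal(gs$observed, 0)
  expect_equal(gs$p, 1)
  for (metric in c("degree", "betweenness")) {
    ct <- centrality_test(study, "A", "B", metric = metric)
    expect_true(all(ct$observed == 0))
    expect_true(all(ct$p == 1))
  }
})

test_that("permutation p-values are in (0, 1] and exhaustive at 5+5", {
  study <- two_group_study(seed = 7)
  ed <- edge_difference_test(study, "A", "B")
  expect_true(attr(ed, "exhaustive"))
  expect_equal(attr(ed, "B"), 252)
  expect_true(all(ed$p > 0 & ed$p <= 1))
  # exhaustive p is a multiple of 1/252
  expect_true(all(abs(ed$p * 252 - round(ed$p * 252)) < 1e-9))
})

test_that("swapping group order negates observations, keeps p", {
  study <- two_group_study(seed = 19)
  ab <- edge_difference_test(study, "A", "B")
  ba <- edge_difference_test(study, "B", "A")
  expect_equal(ab$observed, -ba$observed)
  expect_equal(ab$p, ba$p)
  gs_ab <- global_strength_test(study, "A", "B")
  gs_ba <- global_strength_test(study, "B", "A")
  expect_equal(gs_ab$observed, -gs_ba$observed)
  expect_equal(gs_ab$p, gs_ba$p)
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  study <- two_group_study(n = 3, k = 3, seed = 23)
  ex <- global_strength_test(study, "A", "B")   # 20 assignments
  expect_true(attr(ex, "exhaustive"))
  mc <- global_strength_test(study, "A", "B", B = 4000, seed = 5,
                             force_monte_carlo = TRUE)
  tol <- 2 * sqrt(ex$p * (1 - ex$p) / 4000) + 2 / 4001
  expect_lt(abs(mc$p - ex$p), tol + 1e-12)
})

test_that("exhaustive null ranks are uniform for a continuous statistic", {
  # under exchangeability the observed statistic is one of the 20
  # enumerated values, so its exhaustive p must be k/20 for some k
  set.seed(123)
  ps <- replicate(40, {
    study <- two_group_study(n = 3, k = 3, seed = sample.int(1e6, 1))
    global_strength_test(study, "A", "B")$p
  })
  expect_true(all(abs(ps * 20 - round(ps * 20)) < 1e-9))
  # roughly uniform: mean of U{1/20..1} is 0.525
  expect_equal(mean(ps), 0.525, tolerance = 0.12)
})

test_that("an injected strong edge difference is detected", {
  tpl <- study_template("edge_difference", n_animals = 20,
                        pair = c("LSV", "Tu"), delta_r = 0.9)
  gen <- generate_study(tpl, seed = 10)
  ed <- edge_difference_test(gen$study, "A", "B", B = 500, seed = 11)
  hit <- ed[ed$roi1 == "LSV" & ed$roi2 == "Tu", ]
  expect_gt(hit$observed, 0.5)
  expect_lte(hit$p, 0.05)
})

test_that("a hub concentrated in one group is caught by the degree test", {
  reg <- small_registry(6)
  set.seed(33)
  n <- 20
  hub <- rnorm(n)
  mA <- sapply(1:6, function(i) 0.9 * hub + sqrt(1 - 0.81) * rnorm(n))
  colnames(mA) <- registry_rois(reg)
  mB <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, registry_rois(reg)))
  study <- study_from_matrices(list(A = mA, B = mB), reg)
  ct <- centrality_test(study, "A", "B", metric = "degree", B = 300,
                        seed = 3)
  expect_true(any(ct$p <= 0.05))
  expect_gt(max(ct$observed), 0)
})

test_that("compare_groups assembles all units exactly once", {
  tpl <- study_template("null", registry = small_registry(5), n_animals = 5)
  study <- generate_study(tpl, seed = 77)$study
  cp <- compare_groups(study, "VEH/VEH", "KET/VEH")
  expect_equal(nrow(cp$edges), 5 * 4 / 2)
  expect_equal(nrow(cp$global_strength), 1)
  expect_equal(nrow(cp$degree), 5)
  expect_equal(nrow(cp$betweenness), 5)
  td <- tidy(cp)
  expect_equal(nrow(td), 10 + 1 + 5 + 5)
  expect_false(any(duplicated(paste(td$statistic, td$unit))))
  gl <- glance(cp)
  expect_true(gl$exhaustive)
  expect_equal(gl$B, 252)

  # shared-permutation results match the standalone tests (both exhaustive)
  ed <- edge_difference_test(study, "VEH/VEH", "KET/VEH")
  expect_equal(cp$edges$p, ed$p)
  expect_equal(cp$edges$observed, ed$observed)
  bt <- centrality_test(study, "VEH/VEH", "KET/VEH", metric = "betweenness")
  expect_equal(cp$betweenness$p, bt$p)

  # full-size bookkeeping at 33 ROIs
  tpl2 <- study_template("null", n_animals = 5)
  study2 <- generate_study(tpl2, seed = 5)$study
  cp2 <- compare_groups(study2, "VEH/VEH", "VEH/ASE")
  expect_equal(nrow(cp2$edges), 528)
  expect_equal(nrow(tidy(cp2)), 528 + 1 + 2 * 33)
})

test_that("self-comparison yields no significant units", {
  tpl <- study_template("null", registry = small_registry(4), n_animals = 5)
  study <- generate_study(tpl, seed = 13)$study
  cp <- compare_groups(study, "VEH/VEH", "VEH/VEH")
  td <- tidy(cp)
  expect_false(any(td$significant))
  expect_true(all(td$p == 1))
  expect_equal(sum(abs(signed_differences(cp))), 0)
})

test_that("signed-difference matrix carries the sign of significant edges", {
  tpl <- study_template("edge_difference", registry = small_registry(4),
                        pair = c("R1", "R2"), delta_r = 0.95,
                        n_animals = 30)
  gen <- generate_study(tpl, seed = 4)
  cp <- compare_groups(gen$study, "A", "B", B = 300, seed = 9)
  m <- signed_differences(cp)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(m["R1", "R2"], 1L)   # r higher in group A
})

test_that("comparison report files round-trip the significant edges", {
  study <- two_group_study(seed = 3)
  cp <- compare_groups(study, "A", "B")
  dir <- withr::local_tempdir()
  paths <- write_comparison_report(cp, dir)
  expect_true(all(file.exists(paths)))
  nodes <- read.csv(paths["nodes"])
  expect_equal(nrow(nodes), 2 * 4)
  summ <- jsonlite::read_json(paths["summary"])
  expect_equal(summ$B, 252)
})
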