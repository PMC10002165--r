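test_that("default registry holds the 33 analysis ROIs with gcc reference", {
  reg <- roi_registry()
  expect_s3_class(reg, "roi_registry")
  expect_equal(nrow(reg), 33)
  expect_equal(reg$roi[1], "LSV")
  expect_equal(reg$roi[33], "S1jO")
  expect_false(anyDuplicated(reg$roi) > 0)
  expect_equal(reference_roi(reg), "gcc")
  expect_false("gcc" %in% reg$roi)
})

test_that("registry rejects duplicate ROIs and reference among analysis ROIs", {
  bad <- tibble::tibble(roi = c("A", "A"), region = c("x", "y"))
  expect_error(roi_registry(bad), class = "iegnet_validation_error")
  ok <- tibble::tibble(roi = c("A", "B"), region = c("x", "y"))
  expect_error(roi_registry(ok, reference_roi = "A"),
               class = "iegnet_validation_error")
})

test_that("long-table reading preserves rows and validates content", {
  reg <- small_registry(2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,group,roi,section,value",
               "a1,G1,R1,1,1.0", "a1,G1,R1,2,1.2",
               "a1,G1,R2,1,0.5", "a1,G1,R2,2,0.7"), path)
  meas <- read_expression_long(path, reg)
  expect_equal(nrow(meas), 4)
  expect_setequal(unique(meas$roi), c("R1", "R2"))

  # unknown ROI
  writeLines(c("animal_id,group,roi,section,value", "a1,G1,XYZ,1,1.0"), path)
  expect_error(read_expression_long(path, reg),
               class = "iegnet_validation_error")

  # missing column
  writeLines(c("animal_id,group,roi,value", "a1,G1,R1,1.0"), path)
  expect_error(read_expression_long(path, reg),
               class = "iegnet_format_error")

  # negative value
  writeLines(c("animal_id,group,roi,section,value", "a1,G1,R1,1,-1"), path)
  expect_error(read_expression_long(path, reg),
               class = "iegnet_validation_error")

  # unknown group label when a whitelist is given
  writeLines(c("animal_id,group,roi,section,value", "a1,BAD,R1,1,1.0"), path)
  expect_error(read_expression_long(path, reg, groups = c("G1", "G2")),
               class = "iegnet_validation_error")
})

test_that("write-then-read round-trips a synthetic dataset", {
  tpl <- study_template("null", n_animals = 3)
  gen <- generate_study(tpl, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_long(gen$measurements, path)
  back <- read_expression_long(path, roi_registry())
  orig <- dplyr::arrange(gen$measurements, animal, roi, section)
  back <- dplyr::arrange(back, animal, roi, section)
  expect_equal(back$value, orig$value, tolerance = 1e-12)
  expect_equal(back$roi, orig$roi)
  expect_equal(back$animal, orig$animal)
  expect_equal(nrow(back), nrow(orig))
})

test_that("section averaging uses the sample mean and sd", {
  df <- tibble::tibble(animal = "a1", group = "G", roi = "R1",
                       section = 1:3, value = c(1, 2, 3))
  out <- average_sections(df)
  expect_equal(out$value, 2)
  expect_equal(out$sd, 1)

  one <- tibble::tibble(animal = "a1", group = "G", roi = "R1",
                        section = 1, value = 5)
  expect_warning(res <- average_sections(one), "replicate count")
  expect_equal(res$value, 5)
  expect_equal(res$sd, 0)

  tri <- tibble::tibble(animal = "a1", group = "G", roi = "R1",
                        section = 1:3, value = c(2, 4, 9))
  res <- average_sections(tri)
  expect_equal(res$value, 5)
  expect_equal(res$sd, sd(c(2, 4, 9)))  # sqrt(13)
  expect_equal(res$sd^2, 13)

  expect_error(average_sections(df[0, ]), class = "iegnet_validation_error")
})

test_that("reference normalization divides (or subtracts) per animal", {
  reg <- small_registry(2)
  averaged <- tibble::tibble(
    animal = rep(c("a1", "a2", "a3"), each = 3),
    group = "G1",
    roi = rep(c("R1", "R2", "gcc"), 3),
    value = c(100, 150, 100,  50, 80, 100,  30, 60, 60)
  )
  study <- normalize_by_reference(averaged, reg, mode = "ratio")
  m <- expression_table(study, "G1")
  expect_equal(m["a1", "R1"], 1.0)   # equals its own reference
  expect_equal(m["a1", "R2"], 1.5)   # 150 / 100
  expect_equal(m["a3", "R2"], 1.0)
  expect_false("gcc" %in% colnames(m))
  expect_equal(colnames(m), registry_rois(reg))

  sub <- normalize_by_reference(averaged, reg, mode = "subtract")
  ms <- expression_table(sub, "G1")
  expect_equal(ms["a1", "R2"], 50)

  averaged$value[3] <- 0
  expect_error(normalize_by_reference(averaged, reg, mode = "ratio"),
               "a1", class = "iegnet_validation_error")
})

test_that("ratio normalization is invertible given the reference values", {
  reg <- small_registry(3)
  set.seed(42)
  averaged <- tibble::tibble(
    animal = rep(paste0("a", 1:4), each = 4),
    group = "G1",
    roi = rep(c(registry_rois(reg), "gcc"), 4),
    value = runif(16, 0.5, 2)
  )
  study <- normalize_by_reference(averaged, reg)
  refs <- averaged$value[averaged$roi == "gcc"]
  names(refs) <- averaged$animal[averaged$roi == "gcc"]
  recovered <- study$value * refs[study$animal]
  orig <- averaged[averaged$roi != "gcc", ]
  key <- paste(orig$animal, orig$roi)
  expect_equal(unname(recovered[match(paste(study$animal, study$roi), key)]),
               orig$value[match(paste(study$animal, study$roi), key)],
               tolerance = 1e-12)
})

test_that("study tables are complete and registry-ordered", {
  tpl <- study_template("null", n_animals = 4)
  study <- generate_study(tpl, seed = 3)$study
  for (g in study_groups(study)) {
    m <- expression_table(study, g)
    expect_equal(dim(m), c(4, 33))
    expect_equal(colnames(m), registry_rois(roi_registry()))
  }
  # missing cell is a hard error
  broken <- study[-1, ]
  expect_error(ieg_study(broken, roi_registry()),
               class = "iegnet_validation_error")
})
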