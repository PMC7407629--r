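test_that("a .dat bundle is read with rows and columns in file order", {
  dir <- write_tiny_bundle()
  ft <- read_dat_bundle(dir)
  expect_s3_class(ft, "feature_table")
  expect_identical(ft$sample_ids, c("s1", "s2"))
  expect_identical(ft$mz, c(100, 200, 300))
  expect_identical(ft$rt, c(1, 2, 3))
  expect_identical(unname(ft$intensities), rbind(c(1, 0, 2), c(0, 5, 0)))
})

test_that("an all-zero retention-time file is accepted and is metadata only", {
  dir <- write_tiny_bundle()
  writeLines("0 0 0", file.path(dir, "Variables_t.dat"))
  ft0 <- read_dat_bundle(dir)
  expect_identical(ft0$rt, c(0, 0, 0))
  expect_identical(nrow(validate_feature_table(ft0)), 0L)
  # same intensities, different rt: identical distances hence identical trees
  sim <- simulate_feature_table(synthetic_spec(
    n_groups = 2, samples_per_group = 3, n_core_features = 8,
    n_group_features = 4, n_noise_features = 20, seed = 5))
  t1 <- sim$table
  t2 <- feature_table(t1$sample_ids, t1$mz, rep(0, length(t1$rt)), t1$intensities)
  f1 <- hcapca(t1)
  f2 <- hcapca(t2)
  expect_identical(lapply(f1$nodes, `[[`, "members"),
                   lapply(f2$nodes, `[[`, "members"))
})

test_that("malformed bundles fail with named errors", {
  dir <- write_tiny_bundle()
  file.remove(file.path(dir, "Table.dat"))
  expect_error(read_dat_bundle(dir), "missing bundle member.*Table\\.dat")

  dir <- write_tiny_bundle()
  writeLines(c("1 0 2", "0 5 0", "9 9 9"), file.path(dir, "Table.dat"))
  expect_error(read_dat_bundle(dir), "dimension error.*3 rows.*2 sample")

  dir <- write_tiny_bundle()
  writeLines(c("1 0", "0 5"), file.path(dir, "Table.dat"))
  expect_error(read_dat_bundle(dir), "dimension error.*row 1.*2 values")

  dir <- write_tiny_bundle()
  writeLines(c("1 x 2", "0 5 0"), file.path(dir, "Table.dat"))
  expect_error(read_dat_bundle(dir), "parse error.*line 1, token 2")

  dir <- write_tiny_bundle()
  writeLines(c("s1", "", "s2"), file.path(dir, "Analyses.dat"))
  expect_error(read_dat_bundle(dir), "blank")
})

test_that("write/read round trip is the identity on random tables", {
  for (seed in 1:5) {
    ft <- random_table(S = 4, F = 7, seed = seed)
    dir <- tempfile("rt")
    write_dat_bundle(ft, dir)
    back <- read_dat_bundle(dir)
    expect_identical(back$sample_ids, ft$sample_ids)
    expect_equal(back$mz, ft$mz, tolerance = 1e-9)
    expect_equal(back$rt, ft$rt, tolerance = 1e-9)
    expect_equal(unname(back$intensities), unname(ft$intensities), tolerance = 1e-9)
  }
  one <- random_table(S = 1, F = 3, seed = 99)
  dir <- tempfile("one")
  write_dat_bundle(one, dir)
  expect_length(readLines(file.path(dir, "Table.dat")), 1L)
  empty <- list(sample_ids = "s1", mz = numeric(0), rt = numeric(0),
                intensities = matrix(0, 1, 0))
  expect_error(write_dat_bundle(empty, tempfile()), "0 features")
})

test_that("MZmine-style CSV import transposes, fills blanks, checks mapping", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    'row m/z,row retention time,sA Peak area,sB Peak area',
    '100.5,1.2,10,20',
    '200.5,2.2,,30',
    '300.5,3.2,50,60'), csv)
  ft <- import_feature_csv(csv)
  expect_identical(ft$sample_ids, c("sA", "sB"))
  expect_identical(dim(ft$intensities), c(2L, 3L))
  expect_identical(unname(ft$intensities["sA", 2]), 0)  # blank cell -> 0
  expect_identical(ft$mz, c(100.5, 200.5, 300.5))

  writeLines(c('row m/z,row retention time,foo,bar', '1,1,2,3'), csv)
  expect_error(import_feature_csv(csv), "mapping error")
  writeLines(c('row m/z,row retention time,sA Peak area,sA Peak area',
               '1,1,2,3'), csv)
  expect_error(import_feature_csv(csv), "uniqueness error")
})

test_that("validation reports one finding per violated invariant with coordinates", {
  ft <- feature_table(c("a", "b"), c(1, 2), c(1, 2), rbind(c(1, 2), c(3, 4)))
  expect_identical(nrow(validate_feature_table(ft)), 0L)

  bad <- ft
  bad$intensities[2, 1] <- -5
  f <- validate_feature_table(bad)
  expect_identical(nrow(f), 1L)
  expect_identical(f$row, 2L)
  expect_identical(f$col, 1L)

  bad <- ft
  bad$sample_ids <- c("a", "a")
  rownames(bad$intensities) <- bad$sample_ids
  f <- validate_feature_table(bad)
  expect_identical(f$invariant, "unique_sample_ids")
  expect_match(f$message, "'a'")
})
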