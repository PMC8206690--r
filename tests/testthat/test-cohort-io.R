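# Cohort data model and long-epoch-table round trips.

test_that("a written cohort reads back identically", {
  set.seed(42)
  coh <- random_cohort(n_per_group = 3L, nights = 3L, n_epochs = 50L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(names(back$subjects), names(coh$subjects))
  for (id in names(coh$subjects)) {
    expect_identical(back$subjects[[id]]$group, coh$subjects[[id]]$group)
    expect_identical(lapply(back$subjects[[id]]$nights, as.integer),
                     lapply(coh$subjects[[id]]$nights, as.integer))
  }
})

test_that("tab-delimited output round-trips too", {
  coh <- make_cohort(
    a = list(group = "CI", nights = list(`1` = as.integer(0:29))),
    b = list(group = "healthy", nights = list(`1` = rep(0L, 480),
                                              `2` = rep(0L, 480))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path, sep = "\t")
  back <- read_cohort(path)
  expect_identical(back$subjects$a$nights[["1"]], as.integer(0:29))
  expect_identical(night_table(back)$tib_minutes, c(30L, 480L, 480L))
})

test_that("boundary validation rejects exactly the invalid inputs", {
  ok <- list(`1` = rep(0L, 20))
  expect_s3_class(make_cohort(a = list(group = "CI", nights = ok),
                              b = list(group = "healthy", nights = ok)),
                  "actigraphy_cohort")
  # negative count, citing the position
  bad <- list(`1` = c(rep(0L, 19), -1L))
  expect_error(make_cohort(a = list(group = "CI", nights = bad)),
               "negative count at epoch 19")
  # non-integer count
  expect_error(make_cohort(a = list(group = "CI",
                                    nights = list(`1` = c(rep(0, 19), 0.5)))),
               "non-integer")
  # short night
  expect_error(make_cohort(a = list(group = "CI",
                                    nights = list(`1` = rep(0L, 19)))),
               "minimum is 20")
  # no nights
  expect_error(make_cohort(a = list(group = "CI", nights = list())),
               "at least one night")
  # bad group label
  expect_error(make_cohort(a = list(group = "case", nights = ok)),
               "group must be")
  # duplicate night index
  expect_error(make_cohort(a = list(group = "CI",
                                    nights = stats::setNames(
                                      list(rep(0L, 20), rep(0L, 20)),
                                      c("1", "1")))),
               "duplicate night_index")
})

test_that("file-level errors name the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,night_index,count", "a,CI,1,0"), path)
  expect_error(read_cohort(path), "missing column")
  # non-contiguous epoch_index
  hdr <- "subject_id,group,night_index,epoch_index,count"
  rows <- sprintf("a,CI,1,%d,0", c(0:9, 11:20))
  writeLines(c(hdr, rows), path)
  expect_error(read_cohort(path), "not contiguous")
  # negative count cites subject/night/epoch
  rows <- sprintf("a,CI,1,%d,%d", 0:19, c(rep(0L, 12), -3L, rep(0L, 7)))
  writeLines(c(hdr, rows), path)
  expect_error(read_cohort(path), "subject a night 1.*epoch 12")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("feature matrix round-trips at full precision", {
  set.seed(7)
  coh <- random_cohort(n_per_group = 2L, nights = 2L, n_epochs = 60L)
  fm <- night_feature_matrix(coh)
  expect_equal(ncol(fm), 3L + 48L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_identical(names(back), names(fm))
  for (cn in feature_names())   # full printed precision (15 sig digits)
    expect_equal(as.numeric(back[[cn]]), as.numeric(fm[[cn]]),
                 tolerance = 1e-12)
  # header-only file for zero rows
  write_feature_matrix(fm[0L, , drop = FALSE], path)
  expect_identical(readLines(path),
                   paste(names(fm), collapse = ","))
  expect_error(write_feature_matrix(fm[, -1L, drop = FALSE], path),
               "must carry columns")
})

test_that("truncate_nights keeps each subject's earliest k nights", {
  coh <- make_cohort(
    a = list(group = "CI",
             nights = stats::setNames(replicate(4, rep(0L, 20),
                                                simplify = FALSE),
                                      c("2", "4", "1", "3"))),
    b = list(group = "healthy", nights = list(`1` = rep(0L, 20))))
  tr <- truncate_nights(coh, 2L)
  expect_setequal(names(tr$subjects$a$nights), c("1", "2"))
  expect_identical(names(tr$subjects$b$nights), "1")
})
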