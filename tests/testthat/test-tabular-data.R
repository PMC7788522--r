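test_that("labeled tables are read from delimited files with the label in the last column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "NPTXR_23467,DOCK3_1795,LOC400927_400927,her2_status",
    "266.0075,38.1356,12.7119,Negative",
    "461.8575,34.9231,6.5481,Negative",
    "199.3335,11.8146,6.9676,Positive"
  ), path)
  tab <- read_labeled_table(path)
  expect_s3_class(tab, "labeled_table")
  expect_equal(nrow(tab$values), 3)
  expect_equal(tab$attribute_names,
               c("NPTXR_23467", "DOCK3_1795", "LOC400927_400927"))
  expect_equal(unname(tab$values[1, 1]), 266.0075)
  expect_equal(tab$labels, c("Negative", "Negative", "Positive"))
  expect_equal(tab$class_levels, c("Negative", "Positive"))
  expect_equal(tab$label_name, "her2_status")
})

test_that("delimiter auto-detection handles tabs, and single-class tables fail only at train time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tclass", "1\t2\tNegative", "3\t4\tNegative"), path)
  tab <- read_labeled_table(path)
  expect_equal(tab$class_levels, "Negative")
  expect_error(fit_nb(tab), "exactly 2 classes")
  expect_error(fit_forest(tab), "exactly 2 classes")
})

test_that("reader rejects malformed files", {
  missing <- file.path(tempdir(), "does-not-exist.csv")
  expect_error(read_labeled_table(missing), "not found")

  one_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("class", "A", "B"), one_col)
  expect_error(read_labeled_table(one_col), "at least one attribute")

  non_numeric <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,class", "1,x,A", "2,3,B"), non_numeric)
  expect_error(read_labeled_table(non_numeric), "non-numeric.*b")
})

test_that("write/read round-trip is the identity on values and labels", {
  set.seed(42)
  tab <- labeled_table(matrix(rnorm(40) * 10^sample(-3:3, 40, TRUE), 10, 4),
                       sample(c("A", "B"), 10, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_table(tab, path)
  back <- read_labeled_table(path)
  expect_identical(back$values, tab$values)
  expect_identical(back$labels, tab$labels)
})

test_that("test-set reader detaches a trailing label column deterministically", {
  pair <- her2_like_pair(seed = 3, n_features = 4)
  train_path <- withr::local_tempfile(fileext = ".csv")
  test_path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_table(pair$train, train_path)
  write_labeled_table(pair$test, test_path)
  train <- read_labeled_table(train_path)

  with_labels <- read_test_table(test_path, train)
  expect_s3_class(with_labels, "unlabeled_table")
  expect_equal(nrow(with_labels$values), 62)
  expect_equal(with_labels$truth, pair$test$labels)

  # same file without the label column -> no detached truth
  bare_path <- withr::local_tempfile(fileext = ".csv")
  df <- read.csv(test_path, check.names = FALSE)
  write.csv(df[, -ncol(df)], bare_path, row.names = FALSE, quote = FALSE)
  bare <- read_test_table(bare_path, train)
  expect_null(bare$truth)
  expect_equal(bare$values, with_labels$values)
})

test_that("test-set reader names the offending column on attribute mismatch", {
  pair <- her2_like_pair(seed = 3, n_features = 4)
  train_path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_table(pair$train, train_path)
  train <- read_labeled_table(train_path)

  bad_path <- withr::local_tempfile(fileext = ".csv")
  df <- read.csv(train_path, check.names = FALSE)
  names(df)[2] <- "renamed_gene"
  write.csv(df, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(read_test_table(bad_path, train), "renamed_gene")
})

test_that("prediction files have one row per instance plus a header", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions("Sample1", "Negative", path)
  expect_equal(length(readLines(path)), 2)

  write_predictions(paste0("Sample", 1:62), rep(c("Negative", "Positive"), 31),
                    path)
  expect_equal(length(readLines(path)), 63)

  write_predictions(character(0), character(0), path)
  expect_equal(length(readLines(path)), 1)

  expect_error(write_predictions(c("a", "b"), "A", path), "equal length")
})
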