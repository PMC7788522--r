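test_that("classification rate is the correct fraction, including the published-layout matrices", {
  expect_equal(classification_rate(c(rep("A", 9), "B"), rep("A", 10)), 0.9)
  # diagonal sums over the two 62-instance confusion matrices of the
  # worked independent-test example
  expect_equal((51 + 3) / 62, 0.870967741935484, tolerance = 1e-12)
  expect_equal((47 + 1) / 62, 0.774193548387097, tolerance = 1e-12)
  pred_nb <- c(rep("Negative", 51), rep("Positive", 0),  # truth Negative
               rep("Negative", 8), rep("Positive", 3))   # truth Positive
  truth <- c(rep("Negative", 51), rep("Positive", 11))
  expect_equal(classification_rate(pred_nb, truth), 54 / 62)
  expect_error(classification_rate(character(0), character(0)), "empty")
  expect_error(classification_rate("A", c("A", "B")), "equal length")
})

test_that("confusion matrices are predicted x truth and conserve the instance count", {
  perfect <- confusion_matrix(rep(c("A", "B"), c(5, 5)),
                              rep(c("A", "B"), c(5, 5)))
  expect_identical(unname(diag(perfect)), c(5L, 5L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  all_a <- confusion_matrix(rep("A", 5), c("A", "A", "A", "B", "B"),
                            c("A", "B"))
  expect_identical(unname(all_a["A", ]), c(3L, 2L))
  expect_identical(unname(all_a["B", ]), c(0L, 0L))

  set.seed(1)
  pred <- sample(c("A", "B"), 37, TRUE)
  truth <- sample(c("A", "B"), 37, TRUE)
  expect_equal(sum(confusion_matrix(pred, truth)), 37)

  expect_error(confusion_matrix("C", "A", c("A", "B")), "outside class_levels")
})

test_that("independent tests report a full confusion matrix and reduce to plain methods on balanced data", {
  pair <- her2_like_pair(seed = 5, n_features = 6)
  report <- independent_test(pair$train, pair$test, "MSNaiveBayes", seed = 2)
  expect_equal(sum(report$confusion), 62)
  expect_equal(report$rate,
               classification_rate(report$predictions, pair$test$labels))
  rep2 <- independent_test(pair$train, pair$test, "MSNaiveBayes", seed = 2)
  expect_identical(report$predictions, rep2$predictions)

  # balanced training data: the MS method is the plain method (m = 0)
  bal <- random_table(3, n_major = 15, n_minor = 15, n_attr = 3)
  test_tab <- random_table(4, n_major = 8, n_minor = 4, n_attr = 3)
  ms <- independent_test(bal, test_tab, "MSNaiveBayes", seed = 10)
  plain <- independent_test(bal, test_tab, "NaiveBayes", seed = 10)
  expect_identical(ms$predictions, plain$predictions)
})

test_that("stratified k-fold CV yields k rates per repeat and leaks no synthetic rows", {
  pair <- her2_like_pair(seed = 9, n_features = 5)
  cv <- kfold_cv(pair$train, "MSNaiveBayes", k = 10, repeats = 3, seed = 21)
  expect_length(cv$rates, 30)
  expect_true(all(cv$rates >= 0 & cv$rates <= 1))
  expect_equal(nrow(cv$details), 30)
  # held-out folds contain no synthetic instances; balanced training folds do
  expect_true(all(cv$details$n_test_synthetic == 0))
  expect_true(all(cv$details$n_train_synthetic > 0))
  # each training fold is balanced to equal class counts: 2 * majority size
  expect_true(all(cv$details$n_train %% 2 == 0))
  expect_equal(cv$details$n_train - cv$details$n_train_synthetic + cv$details$n_test,
               rep(100, 30))

  expect_error(kfold_cv(pair$train, "MSNaiveBayes", k = 20, seed = 1),
               "at least k")
})

test_that("CV rates hit 1.0 on perfectly separable data for any consistent learner", {
  # majority cluster high, minority cluster low (the fixture-family premise:
  # the minority class occupies the low-intensity region, so median-scaled
  # supplements fall into minority territory, not onto the majority cluster)
  set.seed(1200)
  sep <- labeled_table(
    rbind(matrix(runif(60, 50, 60), ncol = 2),
          matrix(runif(30, 0, 2), ncol = 2)),
    rep(c("High", "Low"), c(30, 15)))
  for (method in c("NaiveBayes", "RandomForest",
                   "MSNaiveBayes", "MSRandomForest")) {
    cv <- kfold_cv(sep, method, k = 5, repeats = 2, seed = 12, n_trees = 50)
    expect_true(all(cv$rates == 1.0), label = method)
  }
})

test_that("Mann-Whitney matches the frozen toy example and is antisymmetric", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)

  swapped <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$U, 3 * 3 - res$U)
  expect_equal(swapped$p_value, res$p_value)

  # identical samples are maximally non-significant (tied, so approximate)
  same <- mann_whitney(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_false(same$exact)
  expect_gt(same$p_value, 0.95)

  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("the exact branch agrees with full enumeration on tie-free samples", {
  set.seed(6)
  for (na in 2:6) {
    for (nb in 2:6) {
      vals <- sample(seq_len(200), na + nb) + runif(na + nb, 0, 0.4)
      a <- vals[seq_len(na)]
      b <- vals[na + seq_len(nb)]
      got <- mann_whitney(a, b)
      want <- enumerate_mw(a, b)
      expect_equal(got$U, want$U, label = paste(na, nb))
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12,
                   label = paste(na, nb))
    }
  }
})

test_that("evaluation reports serialize to delimited summaries", {
  pair <- her2_like_pair(seed = 2, n_features = 4)
  report <- independent_test(pair$train, pair$test, "MSNaiveBayes", seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(report, path)
  lines <- readLines(path)
  expect_match(lines[1], "MSNaiveBayes")
  expect_length(lines, 6)

  cv <- kfold_cv(pair$train, "NaiveBayes", k = 5, repeats = 2, seed = 2)
  write_report(cv, path)
  lines <- readLines(path)
  expect_match(lines[4], "^mean_rate,")
  expect_equal(length(strsplit(sub("rates,", "", lines[7]), ",")[[1]]), 10)
})
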