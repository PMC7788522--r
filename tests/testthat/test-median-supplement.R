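test_that("attribute medians use the middle order statistic and the even-count mean convention", {
  tab <- labeled_table(
    matrix(c(266.0075, 461.8575, 199.3335,
             38.1356, 34.9231, 11.8146,
             7, 7, 7), ncol = 3),
    c("Negative", "Negative", "Positive"),
    attribute_names = c("NPTXR_23467", "DOCK3_1795", "const"))
  med <- attribute_medians(tab)
  expect_equal(unname(med[["NPTXR_23467"]]), 266.0075)
  expect_equal(unname(med[["DOCK3_1795"]]), 34.9231)
  expect_equal(unname(med[["const"]]), 7)

  even <- labeled_table(matrix(c(1, 3), ncol = 1), c("A", "B"))
  expect_equal(unname(attribute_medians(even)[[1]]), 2)
})

test_that("minority-scope medians are computed over the minority class only", {
  tab <- labeled_table(matrix(c(10, 20, 30, 40, 1, 3), ncol = 1),
                       c(rep("A", 4), "B", "B"))
  expect_equal(unname(attribute_medians(tab, "all")[[1]]), median(c(10, 20, 30, 40, 1, 3)))
  expect_equal(unname(attribute_medians(tab, "minority")[[1]]), 2)
  expect_identical(attr(attribute_medians(tab, "minority"), "scope"), "minority")
})

test_that("supplement size is the absolute class-count difference", {
  expect_identical(supplement_size(c(86, 14)), 72L)
  expect_identical(supplement_size(c(1589, 1046)), 543L)
  expect_identical(supplement_size(c(10, 10)), 0L)
  expect_error(supplement_size(c(1, 2, 3)), "two class counts")
})

test_that("supplement values are medians scaled by uniform draws on [0, 1)", {
  empty <- generate_supplement(c(a = 1, b = 2), m = 0, label = "B", seed = 1)
  expect_equal(dim(empty$values), c(0L, 2L))

  zero_med <- generate_supplement(c(a = 0, b = 5), m = 100, label = "B", seed = 2)
  expect_true(all(zero_med$values[, 1] == 0))
  expect_true(all(zero_med$values[, 2] >= 0 & zero_med$values[, 2] < 5))

  # Monte-Carlo check against the closed form: mean = median/2, sd = median/sqrt(12)
  mc <- generate_supplement(c(x = 2.0), m = 10000, label = "B", seed = 3)
  expect_lt(abs(mean(mc$values) - 1.0), 3 * (2.0 / sqrt(12)) / 100)

  expect_error(generate_supplement(c(x = 1), m = -1, label = "B", seed = 1),
               "non-negative")
})

test_that("balance equalizes class counts with minority-labeled synthetic rows and preserves the input", {
  for (seed in 1:200) {
    tab <- random_table(seed, allow_negative = seed %% 3 == 0)
    counts <- class_counts(tab)
    m <- abs(counts[[1]] - counts[[2]])
    bal <- balance(tab, seed = seed + 1000)
    bc <- class_counts(bal)

    expect_equal(bc[[1]], bc[[2]])
    expect_equal(sum(bal$is_synthetic), m)
    expect_equal(nrow(bal$values), 2 * max(counts))
    if (m > 0) {
      expect_true(all(bal$labels[bal$is_synthetic] ==
                        names(counts)[which.min(counts)]))
      # sign-aware range: synthetic values between 0 and the attribute median
      med <- as.numeric(attribute_medians(tab))
      synth <- bal$values[bal$is_synthetic, , drop = FALSE]
      for (j in seq_along(med)) {
        expect_true(all(synth[, j] >= min(0, med[j]) &
                          synth[, j] <= max(0, med[j])))
      }
    }
    # removing synthetic rows recovers the input exactly
    expect_identical(bal$values[!bal$is_synthetic, , drop = FALSE], tab$values)
    expect_identical(bal$labels[!bal$is_synthetic], tab$labels)
  }
})

test_that("balance is a fixed point on balanced input and deterministic in the seed", {
  tab <- random_table(7, n_major = 12, n_minor = 12)
  bal <- balance(tab, seed = 5)
  expect_identical(bal$values, tab$values)
  expect_identical(bal$labels, tab$labels)
  expect_equal(sum(bal$is_synthetic), 0)

  imb <- random_table(8, n_major = 20, n_minor = 6)
  b1 <- balance(imb, seed = 99)
  b2 <- balance(imb, seed = 99)
  b3 <- balance(imb, seed = 100)
  expect_identical(b1$values, b2$values)
  expect_false(identical(b1$values, b3$values))
  # idempotence: re-balancing adds nothing further
  rebal <- balance(labeled_table(b1$values, b1$labels), seed = 101)
  expect_equal(nrow(rebal$values), nrow(b1$values))
})

test_that("minority-scope balancing keeps supplements inside the minority median range", {
  tab <- random_table(21, n_major = 30, n_minor = 8)
  bal <- balance(tab, seed = 1, median_scope = "minority")
  med <- as.numeric(attribute_medians(tab, "minority"))
  synth <- bal$values[bal$is_synthetic, , drop = FALSE]
  for (j in seq_along(med)) {
    expect_true(all(synth[, j] >= min(0, med[j]) & synth[, j] <= max(0, med[j])))
  }
})

test_that("balance rejects degenerate inputs", {
  three <- labeled_table(matrix(1:6, ncol = 1), c("A", "A", "B", "B", "C", "C"))
  expect_error(balance(three, seed = 1), "exactly 2 classes")
})
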