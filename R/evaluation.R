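#' Classification rate
#'
#' Ratio of correctly classified instances to the total number of instances —
#' the sole performance measure used throughout the package.
#'
#' @param predicted Predicted class labels.
#' @param truth True class labels, same length.
#' @return Proportion in `[0, 1]`.
#' @export
classification_rate <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  mean(as.character(predicted) == as.character(truth))
}

#' Confusion matrix (predicted x true)
#'
#' Cross-tabulation with predicted classes in rows and true classes in
#' columns.
#'
#' @param predicted Predicted class labels.
#' @param truth True class labels.
#' @param class_levels The two class levels; defaults to the sorted union of
#'   the observed labels.
#' @return 2x2 integer matrix, rows = predicted, columns = truth.
#' @export
confusion_matrix <- function(predicted, truth, class_levels = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (is.null(class_levels)) class_levels <- sort(unique(c(predicted, truth)))
  unknown <- setdiff(unique(c(predicted, truth)), class_levels)
  if (length(unknown)) {
    stop("label(s) outside class_levels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(predicted, levels = class_levels),
              factor(truth, levels = class_levels))
  m <- matrix(as.integer(cm), nrow = length(class_levels),
              dimnames = list(predicted = class_levels, truth = class_levels))
  m
}

#' Per-class sensitivity from a confusion matrix
#'
#' Proportion of instances truly in `class` that were predicted as `class`.
#'
#' @param cm Confusion matrix from [confusion_matrix()] (predicted x truth).
#' @param class Class level of interest.
#' @return Proportion in `[0, 1]`; `NA` if no instance of `class` is present.
#' @export
class_sensitivity <- function(cm, class) {
  tot <- sum(cm[, class])
  if (tot == 0L) return(NA_real_)
  cm[class, class] / tot
}

resolve_method <- function(method) {
  methods <- c("MSRandomForest", "MSNaiveBayes", "RandomForest", "NaiveBayes")
  if (!is.character(method) || length(method) != 1L || !(method %in% methods)) {
    stop("unknown method '", paste(method, collapse = ","), "'; valid methods: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  method
}

# Fit the requested backend, balancing the training table first for the
# median-supplement (MS*) methods. Seeds for balancing and forest growth are
# derived from the single caller seed.
fit_method <- function(train, method, seed, n_trees = 500L, mtry = NULL,
                       min_node_size = 1L, variance_floor = NULL,
                       median_scope = "all") {
  method <- resolve_method(method)
  seeds <- derive_seeds(seed, 2L)
  if (startsWith(method, "MS")) {
    train <- balance(train, seed = seeds[1L], median_scope = median_scope)
  }
  if (grepl("RandomForest", method)) {
    fit_forest(train, n_trees = n_trees, mtry = mtry,
               min_node_size = min_node_size, seed = seeds[2L])
  } else {
    fit_nb(train, variance_floor = variance_floor)
  }
}

#' Evaluate a method on an independent test set
#'
#' Median-supplement methods balance the training table only; the test set is
#' never touched by the augmentation. The fitted model predicts the test
#' instances and the report carries the predictions, the confusion matrix
#' and the classification rate.
#'
#' @param train Training [labeled_table()].
#' @param test An [unlabeled_table()] carrying `$truth`, or a
#'   [labeled_table()] used as a labeled test set.
#' @param method One of `"MSRandomForest"`, `"MSNaiveBayes"`,
#'   `"RandomForest"`, `"NaiveBayes"`.
#' @param seed Integer seed (balancing draw + forest growth).
#' @param ... Backend hyperparameters passed to [fit_forest()] / [fit_nb()]
#'   via the method dispatcher (`n_trees`, `mtry`, `min_node_size`,
#'   `variance_floor`, `median_scope`).
#' @return Object of class `evaluation_report`: `method`, `seed`,
#'   `predictions`, `truth`, `confusion`, `rate`.
#' @export
independent_test <- function(train, test, method, seed, ...) {
  stopifnot(inherits(train, "labeled_table"))
  if (inherits(test, "labeled_table")) {
    truth <- test$labels
    test <- unlabeled_table(test$values, test$attribute_names, truth = truth)
  }
  stopifnot(inherits(test, "unlabeled_table"))
  if (is.null(test$truth)) stop("test set carries no truth labels", call. = FALSE)
  model <- fit_method(train, method, seed, ...)
  predictions <- predict(model, test)
  cm <- confusion_matrix(predictions, test$truth, train$class_levels)
  structure(list(method = method, seed = as.integer(seed),
                 predictions = predictions, truth = test$truth,
                 confusion = cm,
                 rate = classification_rate(predictions, test$truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$method, "| classification rate",
      sprintf("%.4f", x$rate), "\n")
  print(x$confusion)
  invisible(x)
}

# Stratified fold assignment: within each class, instances are shuffled and
# dealt round-robin into k folds, so every fold keeps both classes
# represented (given each class count >= k).
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Folds are stratified by class. For median-supplement methods, balancing is
#' applied inside each training split only — the held-out fold is always a
#' subset of the original rows, so synthetic instances can never leak into
#' evaluation. One classification rate is recorded per held-out fold, and the
#' whole procedure is repeated `repeats` times with derived seeds.
#'
#' @param table Full [labeled_table()] (unbalanced; balancing happens
#'   per fold).
#' @param method See [independent_test()].
#' @param k Number of folds (each class count must be at least `k`).
#' @param repeats Number of independent repetitions (default 10).
#' @param seed Integer seed; all fold assignments, balancing draws and forest
#'   seeds derive from it.
#' @param ... Backend hyperparameters (see [independent_test()]).
#' @return Object of class `rate_sample`: `rates` (length `k * repeats`),
#'   `method`, `k`, `repeats`, `seed`, and a `details` data frame with one
#'   row per (repeat, fold) recording train/test sizes and synthetic-row
#'   counts.
#' @export
kfold_cv <- function(table, method, k = 10L, repeats = 10L, seed = 1L, ...) {
  stopifnot(inherits(table, "labeled_table"))
  assert_binary(table)
  method <- resolve_method(method)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  counts <- class_counts(table)
  if (any(counts < k)) {
    stop("every class must have at least k = ", k, " instances; counts: ",
         paste(counts, collapse = ", "), call. = FALSE)
  }
  seeds <- derive_seeds(seed, repeats)
  rates <- numeric(0)
  details <- vector("list", repeats * k)
  for (r in seq_len(repeats)) {
    fold_seeds <- derive_seeds(seeds[r], k + 1L)
    fold <- stratified_folds(table$labels, k, fold_seeds[k + 1L])
    for (f in seq_len(k)) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      train <- labeled_table(table$values[train_idx, , drop = FALSE],
                             table$labels[train_idx],
                             attribute_names = table$attribute_names,
                             is_synthetic = table$is_synthetic[train_idx],
                             label_name = table$label_name)
      held_out <- unlabeled_table(table$values[test_idx, , drop = FALSE],
                                  table$attribute_names,
                                  truth = table$labels[test_idx])
      model <- fit_method(train, method, fold_seeds[f], ...)
      train_used <- if (startsWith(method, "MS")) {
        balance(train, seed = derive_seeds(fold_seeds[f], 2L)[1L])
      } else {
        train
      }
      predictions <- predict(model, held_out)
      rate <- classification_rate(predictions, held_out$truth)
      rates <- c(rates, rate)
      details[[(r - 1L) * k + f]] <- data.frame(
        repeat_ = r, fold = f,
        n_train = nrow(train_used$values),
        n_train_synthetic = sum(train_used$is_synthetic),
        n_test = length(test_idx),
        n_test_synthetic = sum(table$is_synthetic[test_idx]),
        rate = rate
      )
    }
  }
  structure(list(rates = rates, method = method, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 details = do.call(rbind, details)),
            class = "rate_sample")
}

#' @export
print.rate_sample <- function(x, ...) {
  cat("<rate_sample>", x$method, "|", x$k, "folds x", x$repeats,
      "repeats | mean rate", sprintf("%.4f", mean(x$rates)), "\n")
  invisible(x)
}

#' Mann-Whitney U comparison of two classification-rate samples
#'
#' Wraps [stats::wilcox.test()]: the exact rank-enumeration p-value is used
#' when the smaller sample has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. Two-sided.
#'
#' @param a,b Numeric vectors of rates, or `rate_sample` objects.
#' @return List with `U` (statistic for sample `a`), `p_value`, `n_a`, `n_b`,
#'   `exact` (whether the exact branch was used).
#' @export
mann_whitney <- function(a, b) {
  if (inherits(a, "rate_sample")) a <- a$rates
  if (inherits(b, "rate_sample")) b <- b$rates
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && min(length(a), length(b)) <= 8L
  res <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  list(U = unname(res$statistic), p_value = res$p.value,
       n_a = length(a), n_b = length(b), exact = use_exact)
}

#' Write an evaluation summary to a delimited file
#'
#' For an `evaluation_report`: method, classification rate, and the confusion
#' matrix. For a `rate_sample`: method, k, repeats, mean/min/max rate and the
#' per-fold rates.
#'
#' @param x An `evaluation_report` or `rate_sample`.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "evaluation_report")) {
    writeLines(c(paste0("method,", x$method),
                 paste0("classification_rate,", fmt_dbl(x$rate)),
                 "confusion_matrix (rows=predicted; cols=truth)",
                 paste0(",", paste(colnames(x$confusion), collapse = ","))), con)
    for (i in seq_len(nrow(x$confusion))) {
      writeLines(paste0(rownames(x$confusion)[i], ",",
                        paste(x$confusion[i, ], collapse = ",")), con)
    }
  } else if (inherits(x, "rate_sample")) {
    writeLines(c(paste0("method,", x$method),
                 paste0("k,", x$k),
                 paste0("repeats,", x$repeats),
                 paste0("mean_rate,", fmt_dbl(mean(x$rates))),
                 paste0("min_rate,", fmt_dbl(min(x$rates))),
                 paste0("max_rate,", fmt_dbl(max(x$rates))),
                 paste0("rates,", paste(fmt_dbl(x$rates), collapse = ","))), con)
  } else {
    stop("unsupported report object", call. = FALSE)
  }
  invisible(path)
}
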