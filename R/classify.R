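#' Train a median-supplement classifier and optionally classify new instances
#'
#' The package's main entry point. With a median-supplement method
#' (`"MSRandomForest"`, the default, or `"MSNaiveBayes"`), the training table
#' is first balanced by appending median-scaled synthetic minority instances
#' ([balance()]) and the backend model is fitted on the balanced data. The
#' plain switches (`"RandomForest"`, `"NaiveBayes"`) fit the same backends
#' without balancing, enabling like-for-like comparisons.
#'
#' @param x Training data: a [labeled_table()] or a data frame whose last
#'   column holds the class labels.
#' @param testset Optional set of new instances to classify: an
#'   [unlabeled_table()], a [labeled_table()], or a data frame (a trailing
#'   label column matching the training labels is detached and ignored for
#'   prediction). `NULL` (default) returns only the fitted model.
#' @param method `"MSRandomForest"` (default), `"MSNaiveBayes"`,
#'   `"RandomForest"` or `"NaiveBayes"`.
#' @param seed Integer seed for the balancing draw and forest growth. When
#'   `NULL`, a seed is drawn and reported via a message so the run stays
#'   reproducible.
#' @param n_trees,mtry,min_node_size Forest hyperparameters (see
#'   [fit_forest()]).
#' @param variance_floor Naive Bayes scale floor (see [fit_nb()]).
#' @param median_scope Median scope for balancing (see [balance()]).
#' @return With `testset = NULL`, the fitted model (`forest_model` or
#'   `nb_model`). Otherwise a named character vector of predicted class
#'   labels (`Sample1`, `Sample2`, ...), with the model in attribute
#'   `"model"`.
#' @export
#' @examples
#' pair <- her2_like_pair(seed = 7)
#' preds <- ms_classify(pair$train, testset = pair$test,
#'                      method = "MSNaiveBayes", seed = 7)
#' table(preds, pair$test$labels)
ms_classify <- function(x, testset = NULL,
                        method = c("MSRandomForest", "MSNaiveBayes",
                                   "RandomForest", "NaiveBayes"),
                        seed = NULL, n_trees = 500L, mtry = NULL,
                        min_node_size = 1L, variance_floor = NULL,
                        median_scope = "all") {
  if (is.data.frame(x)) x <- as_labeled_table(x)
  stopifnot(inherits(x, "labeled_table"))
  if (length(method) > 1L) method <- method[1L]
  method <- resolve_method(method)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
    message("no seed supplied; using seed = ", seed)
  }
  model <- fit_method(x, method, seed, n_trees = n_trees, mtry = mtry,
                      min_node_size = min_node_size,
                      variance_floor = variance_floor,
                      median_scope = median_scope)
  if (is.null(testset)) return(model)
  testset <- coerce_testset(testset, x)
  preds <- predict(model, testset)
  names(preds) <- paste0("Sample", seq_along(preds))
  attr(preds, "model") <- model
  preds
}

coerce_testset <- function(testset, reference) {
  if (inherits(testset, "unlabeled_table")) return(testset)
  if (inherits(testset, "labeled_table")) {
    return(unlabeled_table(testset$values, testset$attribute_names,
                           truth = testset$labels))
  }
  if (is.data.frame(testset)) {
    nms <- names(testset)
    ref <- reference$attribute_names
    if (length(nms) == length(ref) + 1L &&
        (identical(nms[length(nms)], reference$label_name) ||
         all(as.character(testset[[length(nms)]]) %in% reference$class_levels))) {
      truth <- as.character(testset[[length(nms)]])
      testset <- testset[, -length(nms), drop = FALSE]
      return(unlabeled_table(as.matrix(testset), names(testset), truth = truth))
    }
    return(unlabeled_table(as.matrix(testset), nms))
  }
  stop("unsupported testset type", call. = FALSE)
}
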