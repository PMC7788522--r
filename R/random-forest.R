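#' Build a single decision tree
#'
#' Recursive binary partitioning: at each node, `mtry` candidate attributes
#' are drawn at random without replacement and the (attribute, threshold)
#' pair minimizing the weighted Gini impurity of the two children is chosen;
#' thresholds are midpoints between consecutive distinct sorted values of the
#' candidate attribute, with impurity ties broken to the lowest attribute
#' index then the lowest threshold. Nodes that are pure, at or below
#' `min_node_size`, or unsplittable become leaves labeled with their majority
#' class (ties to the first class level).
#'
#' @param table A [labeled_table()] with exactly two classes.
#' @param mtry Number of candidate attributes per split; default all
#'   attributes (deterministic tree).
#' @param min_node_size Stop splitting nodes at or below this size
#'   (default 1).
#' @param seed Optional integer seed for the feature subsampling.
#' @return An object of class `decision_tree` wrapping the node table.
#' @export
build_tree <- function(table, mtry = NULL, min_node_size = 1L, seed = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  assert_binary(table)
  n_attr <- ncol(table$values)
  if (is.null(mtry)) mtry <- n_attr
  check_forest_params(1L, mtry, n_attr)
  y <- match(table$labels, table$class_levels) - 1L
  nodes <- if (is.null(seed)) {
    build_tree_cpp(table$values, y, as.integer(mtry), as.integer(min_node_size))
  } else {
    with_seed(seed, build_tree_cpp(table$values, y, as.integer(mtry),
                                   as.integer(min_node_size)))
  }
  structure(list(nodes = nodes, class_levels = table$class_levels,
                 attribute_names = table$attribute_names,
                 mtry = as.integer(mtry), min_node_size = as.integer(min_node_size)),
            class = "decision_tree")
}

#' @export
predict.decision_tree <- function(object, newdata, ...) {
  model <- list(attribute_names = object$attribute_names)
  x <- as_instance_matrix(model, newdata)
  votes <- forest_votes_cpp(list(object$nodes), x)
  unname(ifelse(votes[, 2L] > votes[, 1L],
                object$class_levels[2L], object$class_levels[1L]))
}

check_forest_params <- function(n_trees, mtry, n_attr) {
  if (n_trees < 1L) stop("number of trees must be at least 1", call. = FALSE)
  if (mtry < 1L || mtry > n_attr) {
    stop("mtry must lie in [1, ", n_attr, "]; got ", mtry, call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a random forest
#'
#' Grows `n_trees` decision trees (see [build_tree()]), each on a bootstrap
#' resample of the training table (same size, drawn with replacement) when
#' `bootstrap = TRUE`, with `mtry` candidate attributes drawn at random at
#' every split. Prediction is by majority vote over the trees. The fit is a
#' pure function of (data, hyperparameters, seed).
#'
#' @param table A [labeled_table()] with exactly two classes.
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidate attributes per split; default
#'   `floor(sqrt(n_attributes))`.
#' @param min_node_size Node size at or below which splitting stops
#'   (default 1).
#' @param seed Integer seed controlling bootstrap draws and feature
#'   subsampling.
#' @param bootstrap Draw a bootstrap resample per tree (default `TRUE`);
#'   `FALSE` grows every tree on the full table.
#' @return Object of class `forest_model`.
#' @export
fit_forest <- function(table, n_trees = 500L, mtry = NULL, min_node_size = 1L,
                       seed = 1L, bootstrap = TRUE) {
  stopifnot(inherits(table, "labeled_table"))
  assert_binary(table)
  n_attr <- ncol(table$values)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(n_attr)))
  check_forest_params(n_trees, mtry, n_attr)
  y <- match(table$labels, table$class_levels) - 1L
  trees <- with_seed(seed, fit_forest_cpp(table$values, y, as.integer(n_trees),
                                          as.integer(mtry),
                                          as.integer(min_node_size),
                                          isTRUE(bootstrap)))
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed), bootstrap = isTRUE(bootstrap),
                 class_levels = table$class_levels,
                 attribute_names = table$attribute_names),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat("<forest_model>", x$n_trees, "trees | mtry", x$mtry, "| classes:",
      paste(x$class_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-class vote counts of a forest
#'
#' @param model A `forest_model`.
#' @param newdata Instances to classify.
#' @return Integer matrix, instances x classes; each row sums to the number
#'   of trees.
#' @export
forest_votes <- function(model, newdata) {
  stopifnot(inherits(model, "forest_model"))
  x <- as_instance_matrix(model, newdata)
  votes <- forest_votes_cpp(model$trees, x)
  colnames(votes) <- model$class_levels
  votes
}

#' Predict classes by majority vote of a forest
#'
#' The label receiving the most tree votes wins; exact vote ties go to the
#' lexicographically first class level.
#'
#' @param object A `forest_model`.
#' @param newdata Instances to classify.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.forest_model <- function(object, newdata, ...) {
  votes <- forest_votes(object, newdata)
  unname(ifelse(votes[, 2L] > votes[, 1L],
                object$class_levels[2L], object$class_levels[1L]))
}

#' Serialize a forest to a structured text document
#'
#' One CSV row per tree node; thresholds are written with 17 significant
#' digits so [read_forest()] reloads the model bit-exactly.
#'
#' @param model A `forest_model`.
#' @param path Output path.
#' @export
write_forest <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  node_df <- do.call(rbind, lapply(seq_along(model$trees), function(b) {
    nodes <- model$trees[[b]]
    data.frame(tree = b, node = seq_len(nrow(nodes)) - 1L,
               feature = as.integer(nodes[, "feature"]),
               threshold = fmt_dbl(nodes[, "threshold"]),
               left = as.integer(nodes[, "left"]),
               right = as.integer(nodes[, "right"]),
               label = as.integer(nodes[, "label"]),
               stringsAsFactors = FALSE)
  }))
  header <- c(
    "# random forest model",
    paste0("# class_levels=", paste(model$class_levels, collapse = ",")),
    paste0("# attribute_names=", paste(model$attribute_names, collapse = ",")),
    paste0("# n_trees=", model$n_trees, " mtry=", model$mtry,
           " min_node_size=", model$min_node_size, " seed=", model$seed,
           " bootstrap=", model$bootstrap)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(node_df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a forest written by [write_forest()]
#'
#' @param path Path to the model document.
#' @return A `forest_model`, bit-identical to the one serialized.
#' @export
read_forest <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("^# ", key, "="), meta)]
    sub(paste0("^# ", key, "="), "", ln)
  }
  class_levels <- strsplit(get_meta("class_levels"), ",", fixed = TRUE)[[1L]]
  attribute_names <- strsplit(get_meta("attribute_names"), ",", fixed = TRUE)[[1L]]
  params_line <- meta[grepl("n_trees=", meta)]
  get_param <- function(key) {
    as_num <- regmatches(params_line,
                         regexpr(paste0(key, "=[^ ]+"), params_line))
    sub(paste0(key, "="), "", as_num)
  }
  df <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                   sep = ",", stringsAsFactors = FALSE,
                   colClasses = c("integer", "integer", "integer", "character",
                                  "integer", "integer", "integer"))
  trees <- lapply(split(df, df$tree), function(td) {
    td <- td[order(td$node), ]
    m <- cbind(feature = td$feature, threshold = as.numeric(td$threshold),
               left = td$left, right = td$right, label = td$label)
    m
  })
  names(trees) <- NULL
  structure(list(trees = trees, n_trees = as.integer(get_param("n_trees")),
                 mtry = as.integer(get_param("mtry")),
                 min_node_size = as.integer(get_param("min_node_size")),
                 seed = as.integer(get_param("seed")),
                 bootstrap = as.logical(get_param("bootstrap")),
                 class_levels = class_levels,
                 attribute_names = attribute_names),
            class = "forest_model")
}
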