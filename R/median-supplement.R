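#' Per-attribute medians of a labeled table
#'
#' Column-wise medians of the attribute matrix, either over all instances
#' (the default) or over the minority class only. The even-count convention
#' is the arithmetic mean of the two middle order statistics
#' ([stats::median()]).
#'
#' @param table A [labeled_table()].
#' @param scope `"all"` (medians over every instance) or `"minority"`
#'   (medians over minority-class instances only).
#' @return An object of class `median_vector`: named numeric vector of
#'   medians with a `scope` attribute.
#' @export
attribute_medians <- function(table, scope = c("all", "minority")) {
  stopifnot(inherits(table, "labeled_table"))
  scope <- match.arg(scope)
  if (nrow(table$values) == 0L) stop("empty table", call. = FALSE)
  vals <- table$values
  if (scope == "minority") {
    cls <- minority_class(table)
    vals <- vals[table$labels == cls, , drop = FALSE]
    if (nrow(vals) == 0L) stop("minority class is empty", call. = FALSE)
  }
  med <- apply(vals, 2, median)
  names(med) <- table$attribute_names
  structure(med, scope = scope, class = c("median_vector", "numeric"))
}

# Minority class level; ties resolved to the lexicographically first level.
minority_class <- function(table) {
  counts <- class_counts(table)
  names(counts)[which.min(counts)]
}

#' Number of supplementary instances needed to balance two classes
#'
#' @param class_counts Vector of exactly two class counts.
#' @return `abs(n1 - n2)`.
#' @export
#' @examples
#' supplement_size(c(86, 14)) # 72
supplement_size <- function(class_counts) {
  if (length(class_counts) != 2L) {
    stop("exactly two class counts required; got ", length(class_counts),
         call. = FALSE)
  }
  as.integer(abs(class_counts[[1]] - class_counts[[2]]))
}

#' Generate a median-scaled supplementary instance block
#'
#' Draws an `m` by `n` matrix of uniform random numbers on `[0, 1)` and
#' scales each column by the corresponding attribute median, so every
#' synthetic value lies between 0 and its attribute median (sign-aware when
#' a median is negative). The block is a pure function of
#' `(medians, m, seed)`.
#'
#' @param medians A `median_vector` from [attribute_medians()], or a named
#'   numeric vector.
#' @param m Number of synthetic instances (non-negative).
#' @param label Class label assigned to every synthetic row.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `supplement_set`: list with `values` (`m` x `n`
#'   matrix), `label`, `seed`, `m`, `n`.
#' @export
generate_supplement <- function(medians, m, label, seed) {
  if (m < 0) stop("m must be non-negative", call. = FALSE)
  m <- as.integer(m)
  med <- as.numeric(medians)
  n <- length(med)
  u <- with_seed(seed, matrix(runif(m * n), nrow = m, ncol = n))
  values <- sweep(u, 2L, med, `*`)
  colnames(values) <- names(medians)
  structure(list(values = values, label = as.character(label),
                 seed = as.integer(seed), m = m, n = n),
            class = "supplement_set")
}

#' Balance a two-class table with median-scaled synthetic minority instances
#'
#' The balancing scheme proceeds in three steps: (1) compute the median of
#' each attribute; (2) scale the columns of an `m` x `n` uniform random
#' matrix by those medians, where `m` is the difference between the two
#' class counts and `n` the number of attributes; (3) append the resulting
#' supplementary instances, labeled with the minority class, to the original
#' table. The output has equal class counts; original rows are preserved
#' unmodified, in order, ahead of the synthetic rows, which are flagged via
#' `is_synthetic`.
#'
#' @param table A [labeled_table()] with exactly two classes, each non-empty.
#' @param seed Integer seed for the uniform random matrix.
#' @param median_scope `"all"` (default): medians over all instances;
#'   `"minority"`: medians over minority-class instances only.
#' @return A [labeled_table()] with equal class counts and `is_synthetic`
#'   flags marking the appended rows.
#' @export
#' @examples
#' tab <- simulate_table(fixture_spec(20, 5, 3, seed = 1))
#' bal <- balance(tab, seed = 42)
#' class_counts(bal)
balance <- function(table, seed, median_scope = c("all", "minority")) {
  stopifnot(inherits(table, "labeled_table"))
  assert_binary(table)
  median_scope <- match.arg(median_scope)
  counts <- class_counts(table)
  if (any(counts == 0L)) stop("each class needs at least one instance", call. = FALSE)
  m <- supplement_size(counts)
  if (m == 0L) {
    return(labeled_table(table$values, table$labels,
                         attribute_names = table$attribute_names,
                         is_synthetic = rep(FALSE, nrow(table$values)),
                         label_name = table$label_name))
  }
  med <- attribute_medians(table, scope = median_scope)
  supp <- generate_supplement(med, m, label = minority_class(table), seed = seed)
  labeled_table(
    rbind(table$values, supp$values),
    c(table$labels, rep(supp$label, m)),
    attribute_names = table$attribute_names,
    is_synthetic = c(rep(FALSE, nrow(table$values)), rep(TRUE, m)),
    label_name = table$label_name
  )
}
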