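#' Labeled data table for binary classification
#'
#' The package's universal input container: a numeric matrix of attribute
#' values (rows are instances, columns are attributes) plus one class label
#' per row. Class levels are kept in lexicographic order, matching the factor
#' ordering R users see when the label column of a data frame is read in.
#'
#' @param values Numeric matrix (or data frame coercible to one); rows are
#'   instances, columns are attributes.
#' @param labels Character vector of class labels, one per row of `values`.
#' @param attribute_names Optional attribute names; defaults to
#'   `colnames(values)` and must contain no duplicates.
#' @param is_synthetic Optional logical flag per row marking rows created by
#'   [balance()]; defaults to all `FALSE`.
#' @param label_name Name of the label column, used when the table is written
#'   out and when a test file carries a trailing label column.
#'
#' @return An object of class `labeled_table`: a list with elements `values`,
#'   `labels`, `attribute_names`, `class_levels`, `is_synthetic`, `label_name`.
#' @export
#' @examples
#' tab <- labeled_table(matrix(rnorm(20), 10, 2), rep(c("A", "B"), 5))
#' class_counts(tab)
labeled_table <- function(values, labels, attribute_names = NULL,
                          is_synthetic = NULL, label_name = "class") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("attribute values contain missing entries", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("number of labels (", length(labels), ") does not match number of ",
         "instances (", nrow(values), ")", call. = FALSE)
  }
  if (is.null(attribute_names)) attribute_names <- colnames(values)
  if (is.null(attribute_names)) {
    attribute_names <- sprintf("attr%02d", seq_len(ncol(values)))
  }
  attribute_names <- as.character(attribute_names)
  if (length(attribute_names) != ncol(values)) {
    stop("attribute_names length does not match number of columns", call. = FALSE)
  }
  if (anyDuplicated(attribute_names)) {
    stop("duplicate attribute names: ",
         paste(unique(attribute_names[duplicated(attribute_names)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(values) <- attribute_names
  rownames(values) <- NULL
  if (is.null(is_synthetic)) is_synthetic <- rep(FALSE, nrow(values))
  stopifnot(is.logical(is_synthetic), length(is_synthetic) == nrow(values))
  structure(
    list(values = values, labels = labels, attribute_names = attribute_names,
         class_levels = sort(unique(labels)), is_synthetic = is_synthetic,
         label_name = label_name),
    class = "labeled_table"
  )
}

#' Unlabeled table of instances to classify
#'
#' @param values Numeric matrix of attribute values.
#' @param attribute_names Optional attribute names.
#' @param truth Optional character vector of known labels (detached from a
#'   test file for scoring); `NULL` when unknown.
#' @return An object of class `unlabeled_table`.
#' @export
unlabeled_table <- function(values, attribute_names = NULL, truth = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("attribute values contain missing entries", call. = FALSE)
  if (is.null(attribute_names)) attribute_names <- colnames(values)
  attribute_names <- as.character(attribute_names)
  colnames(values) <- attribute_names
  if (!is.null(truth)) {
    truth <- as.character(truth)
    stopifnot(length(truth) == nrow(values))
  }
  structure(list(values = values, attribute_names = attribute_names, truth = truth),
            class = "unlabeled_table")
}

#' @export
print.labeled_table <- function(x, ...) {
  cat("<labeled_table> ", nrow(x$values), " instances x ",
      ncol(x$values), " attributes\n", sep = "")
  cc <- class_counts(x)
  cat("classes: ", paste(names(cc), cc, sep = "=", collapse = ", "), "\n", sep = "")
  if (any(x$is_synthetic)) cat("synthetic rows: ", sum(x$is_synthetic), "\n", sep = "")
  invisible(x)
}

#' @export
print.unlabeled_table <- function(x, ...) {
  cat("<unlabeled_table> ", nrow(x$values), " instances x ",
      ncol(x$values), " attributes",
      if (!is.null(x$truth)) " (with detached truth labels)", "\n", sep = "")
  invisible(x)
}

#' Class counts of a labeled table
#'
#' @param table A [labeled_table()].
#' @return Named integer vector of per-class instance counts, in class-level
#'   order.
#' @export
class_counts <- function(table) {
  stopifnot(inherits(table, "labeled_table"))
  counts <- vapply(table$class_levels, function(l) sum(table$labels == l), 0L)
  names(counts) <- table$class_levels
  counts
}

# Exactly-two-classes guard used by every training entry point.
assert_binary <- function(table) {
  k <- length(table$class_levels)
  if (k != 2L) {
    stop("binary classification requires exactly 2 classes; found ", k,
         " (", paste(table$class_levels, collapse = ", "), ")", call. = FALSE)
  }
  invisible(table)
}

#' Coerce a data frame with a trailing label column to a labeled table
#'
#' Mirrors the tabular convention of the input files: attributes in columns,
#' instances in rows, the class of each instance in the last column.
#'
#' @param df A data frame whose last column holds the class labels and whose
#'   remaining columns are numeric attributes.
#' @return A [labeled_table()].
#' @export
as_labeled_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (ncol(df) < 2L) stop("need at least one attribute column plus the label column",
                          call. = FALSE)
  p <- ncol(df)
  vals <- df[, -p, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, TRUE)]
  if (length(bad)) {
    stop("non-numeric attribute column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labeled_table(as.matrix(vals), as.character(df[[p]]),
                attribute_names = names(vals), label_name = names(df)[p])
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_raw_table <- function(path, delimiter) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  df <- read.table(path, header = TRUE, sep = delimiter, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) < 1L) stop("no data rows in ", path, call. = FALSE)
  df
}

#' Read a labeled training table
#'
#' Reads a delimited text file with a header row in the package's tabular
#' convention: attributes in columns, instances in rows, the class label in
#' the last column. The delimiter is auto-detected (comma vs tab) unless
#' given.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects between
#'   comma and tab from the header line.
#' @return A [labeled_table()].
#' @export
read_labeled_table <- function(path, delimiter = NULL) {
  df <- read_raw_table(path, delimiter)
  if (ncol(df) < 2L) {
    stop("training file needs at least one attribute column plus the label column",
         call. = FALSE)
  }
  as_labeled_table(df)
}

#' Read a test table of new instances
#'
#' The test file must carry the same attribute columns (same names, same
#' order) as the reference training table. A trailing extra column is
#' detached as truth labels when it is named like the training label column
#' or contains only known class levels; otherwise the column set must match
#' the attributes exactly.
#'
#' @param path Path to the file.
#' @param reference The training [labeled_table()] the attributes must match.
#' @param delimiter Field delimiter; `NULL` auto-detects.
#' @return An [unlabeled_table()], with `$truth` set when a label column was
#'   detached.
#' @export
read_test_table <- function(path, reference, delimiter = NULL) {
  stopifnot(inherits(reference, "labeled_table"))
  df <- read_raw_table(path, delimiter)
  ref_names <- reference$attribute_names
  nms <- names(df)
  truth <- NULL
  if (length(nms) == length(ref_names) + 1L) {
    last <- df[[length(nms)]]
    label_like <- identical(nms[length(nms)], reference$label_name) ||
      all(as.character(last) %in% reference$class_levels)
    if (!label_like) {
      stop("test file has ", length(nms), " columns but trailing column '",
           nms[length(nms)], "' is not recognisable as a label column",
           call. = FALSE)
    }
    truth <- as.character(last)
    df <- df[, -length(nms), drop = FALSE]
    nms <- names(df)
  }
  if (length(nms) != length(ref_names)) {
    stop("test file has ", length(nms), " attribute columns; training table has ",
         length(ref_names), call. = FALSE)
  }
  mismatch <- which(nms != ref_names)
  if (length(mismatch)) {
    stop("attribute name mismatch at column ", mismatch[1L], ": got '",
         nms[mismatch[1L]], "', expected '", ref_names[mismatch[1L]], "'",
         call. = FALSE)
  }
  bad <- nms[!vapply(df, is.numeric, TRUE)]
  if (length(bad)) {
    stop("non-numeric attribute column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unlabeled_table(as.matrix(df), attribute_names = nms, truth = truth)
}

#' Write a labeled table to a delimited file
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces them exactly.
#'
#' @param table A [labeled_table()].
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @export
write_labeled_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "labeled_table"))
  chr <- matrix(fmt_dbl(table$values), nrow = nrow(table$values),
                dimnames = dimnames(table$values))
  df <- as.data.frame(chr, stringsAsFactors = FALSE, check.names = FALSE)
  df[[table$label_name]] <- table$labels
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write predictions to a two-column delimited file
#'
#' @param ids Instance identifiers (default `Sample1`, `Sample2`, ... by row
#'   number).
#' @param labels Predicted class labels, same length as `ids`.
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @export
write_predictions <- function(ids, labels, path, delimiter = ",") {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (length(ids) != length(labels)) {
    stop("ids and labels must have equal length", call. = FALSE)
  }
  df <- data.frame(instance = ids, predicted_class = labels,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
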