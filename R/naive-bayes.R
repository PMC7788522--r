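#' Fit a Gaussian naive Bayes model
#'
#' Class priors are the empirical class frequencies of the training table;
#' attributes are modeled, conditionally on the class, as independent
#' univariate Gaussians (posterior for a new instance is proportional to the
#' prior times the product of per-attribute densities). Location is the
#' sample mean, scale the unbiased standard deviation (divisor `n - 1`),
#' floored at `variance_floor` so constant attributes keep finite densities.
#'
#' @param table A [labeled_table()] with exactly two classes, each with at
#'   least 2 instances.
#' @param variance_floor Lower bound on every per-class per-attribute
#'   standard deviation. Default `1e-9 * (var(all values) + 1)`.
#' @return Object of class `nb_model`: `class_levels`, `priors`, `means` and
#'   `sds` (class x attribute matrices), `attribute_names`, `variance_floor`.
#' @export
fit_nb <- function(table, variance_floor = NULL) {
  stopifnot(inherits(table, "labeled_table"))
  assert_binary(table)
  counts <- class_counts(table)
  if (any(counts < 2L)) {
    stop("each class needs at least 2 instances to estimate a scale; counts: ",
         paste(counts, collapse = ", "), call. = FALSE)
  }
  if (is.null(variance_floor)) {
    variance_floor <- 1e-9 * (var(as.vector(table$values)) + 1)
  }
  stopifnot(variance_floor > 0)
  levels <- table$class_levels
  n_attr <- ncol(table$values)
  means <- sds <- matrix(NA_real_, nrow = 2L, ncol = n_attr,
                         dimnames = list(levels, table$attribute_names))
  for (cl in levels) {
    sub <- table$values[table$labels == cl, , drop = FALSE]
    means[cl, ] <- colMeans(sub)
    sds[cl, ] <- pmax(apply(sub, 2, sd), variance_floor)
  }
  structure(list(class_levels = levels,
                 priors = counts / sum(counts),
                 means = means, sds = sds,
                 attribute_names = table$attribute_names,
                 variance_floor = variance_floor),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> classes:", paste(x$class_levels, collapse = ", "),
      "| priors:", paste(sprintf("%.4f", x$priors), collapse = ", "),
      "|", length(x$attribute_names), "attributes\n")
  invisible(x)
}

as_instance_matrix <- function(model, instances) {
  x <- if (inherits(instances, "unlabeled_table")) instances$values
       else if (inherits(instances, "labeled_table")) instances$values
       else if (is.data.frame(instances)) as.matrix(instances)
       else instances
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$attribute_names)) {
    stop("instance has ", ncol(x), " attributes; model expects ",
         length(model$attribute_names), call. = FALSE)
  }
  x
}

#' Per-class log-posterior scores (unnormalized)
#'
#' Returns, for each instance, `log P(C_j) + sum_i log density(g_i | C_j)`;
#' the evidence term common to both classes is omitted because it cancels in
#' the class comparison.
#'
#' @param model An `nb_model`.
#' @param instances An [unlabeled_table()], matrix, data frame, or a single
#'   numeric vector of attribute values.
#' @return Numeric matrix, instances x classes.
#' @export
nb_log_posterior <- function(model, instances) {
  stopifnot(inherits(model, "nb_model"))
  x <- as_instance_matrix(model, instances)
  scores <- matrix(NA_real_, nrow = nrow(x), ncol = 2L,
                   dimnames = list(NULL, model$class_levels))
  for (j in 1:2) {
    ll <- dnorm(x,
                mean = matrix(model$means[j, ], nrow(x), ncol(x), byrow = TRUE),
                sd = matrix(model$sds[j, ], nrow(x), ncol(x), byrow = TRUE),
                log = TRUE)
    scores[, j] <- log(model$priors[[j]]) + rowSums(ll)
  }
  scores
}

#' Normalized class posterior probabilities
#'
#' Log-sum-exp normalization of [nb_log_posterior()] scores, so each row
#' sums to 1.
#'
#' @inheritParams nb_log_posterior
#' @return Numeric matrix, instances x classes, rows summing to 1.
#' @export
nb_posterior <- function(model, instances) {
  scores <- nb_log_posterior(model, instances)
  mx <- apply(scores, 1, max)
  w <- exp(scores - mx)
  w / rowSums(w)
}

#' Predict classes with a naive Bayes model
#'
#' The class with the highest posterior probability becomes the class of the
#' instance; exact posterior ties go to the lexicographically first class
#' level.
#'
#' @param object An `nb_model`.
#' @param newdata Instances to classify (see [nb_log_posterior()]).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.nb_model <- function(object, newdata, ...) {
  scores <- nb_log_posterior(object, newdata)
  unname(ifelse(scores[, 2L] > scores[, 1L],
                object$class_levels[2L], object$class_levels[1L]))
}

#' Serialize a naive Bayes model to a human-readable key-value file
#'
#' @param model An `nb_model`.
#' @param path Output path.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  lines <- c(
    "model: gaussian_naive_bayes",
    paste0("class_levels: ", paste(model$class_levels, collapse = ",")),
    paste0("attribute_names: ", paste(model$attribute_names, collapse = ",")),
    paste0("variance_floor: ", fmt_dbl(model$variance_floor)),
    paste0("priors: ", paste(fmt_dbl(model$priors), collapse = ",")),
    vapply(1:2, function(j) {
      paste0("means.", model$class_levels[j], ": ",
             paste(fmt_dbl(model$means[j, ]), collapse = ","))
    }, ""),
    vapply(1:2, function(j) {
      paste0("sds.", model$class_levels[j], ": ",
             paste(fmt_dbl(model$sds[j, ]), collapse = ","))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a naive Bayes model written by [write_nb_model()]
#'
#' @param path Path to the key-value file.
#' @return An `nb_model`.
#' @export
read_nb_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1L], collapse = ": "), "")
  get1 <- function(k) vals[match(k, keys)]
  split_chr <- function(s) strsplit(s, ",", fixed = TRUE)[[1L]]
  split_num <- function(s) as.numeric(split_chr(s))
  levels <- split_chr(get1("class_levels"))
  attrs <- split_chr(get1("attribute_names"))
  means <- rbind(split_num(get1(paste0("means.", levels[1L]))),
                 split_num(get1(paste0("means.", levels[2L]))))
  sds <- rbind(split_num(get1(paste0("sds.", levels[1L]))),
               split_num(get1(paste0("sds.", levels[2L]))))
  dimnames(means) <- dimnames(sds) <- list(levels, attrs)
  priors <- split_num(get1("priors"))
  names(priors) <- levels
  structure(list(class_levels = levels, priors = priors, means = means,
                 sds = sds, attribute_names = attrs,
                 variance_floor = as.numeric(get1("variance_floor"))),
            class = "nb_model")
}
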