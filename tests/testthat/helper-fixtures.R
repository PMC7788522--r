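# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# Random imbalanced two-class table with continuous attributes.
random_table <- function(seed, n_major = NULL, n_minor = NULL, n_attr = NULL,
                         allow_negative = FALSE) {
  set.seed(seed)
  if (is.null(n_major)) n_major <- sample(5:40, 1)
  if (is.null(n_minor)) n_minor <- sample(2:n_major, 1)
  if (is.null(n_attr)) n_attr <- sample(2:6, 1)
  offset <- if (allow_negative) -5 else 0
  vals <- matrix(runif((n_major + n_minor) * n_attr, offset, 10),
                 ncol = n_attr)
  labeled_table(vals, c(rep("A", n_major), rep("B", n_minor)))
}

# The two-class, one-attribute toy model: class A values (0, 1, 2), class B
# values (4, 5, 6). Equal priors, unit sds, means 1 and 5.
toy_nb_table <- function() {
  labeled_table(matrix(c(0, 1, 2, 4, 5, 6), ncol = 1),
                c("A", "A", "A", "B", "B", "B"),
                attribute_names = "x")
}

# 1-D linearly separable toy data: A at {1,2,3}, B at {10,11,12}.
separable_table <- function() {
  labeled_table(matrix(c(1, 2, 3, 10, 11, 12), ncol = 1),
                c("A", "A", "A", "B", "B", "B"),
                attribute_names = "x")
}

# Independent brute-force Gaussian-Bayes oracle in plain (non-log)
# arithmetic: empirical priors, sample mean/unbiased sd per class, posterior
# by direct density products.
brute_force_nb_posterior <- function(table, x) {
  levels <- sort(unique(table$labels))
  joint <- vapply(levels, function(cl) {
    sub <- table$values[table$labels == cl, , drop = FALSE]
    prior <- nrow(sub) / nrow(table$values)
    dens <- prod(vapply(seq_along(x), function(i) {
      stats::dnorm(x[i], mean = mean(sub[, i]), sd = stats::sd(sub[, i]))
    }, 0))
    prior * dens
  }, 0)
  joint / sum(joint)
}

# Full-enumeration Mann-Whitney oracle for tie-free samples: two-sided
# p-value from the exact permutation distribution of U over all
# choose(na+nb, na) equally likely rank assignments.
enumerate_mw <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  all_ranks <- seq_len(na + nb)
  u_all <- apply(combos, 2, function(idx) sum(all_ranks[idx]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu))
  list(U = u_obs, p_value = min(1, p))
}
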