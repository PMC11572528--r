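# Independent brute-force oracles and small fixtures shared across tests.
# Each oracle is coded directly from the defining formula, separately from the
# package implementation it checks.

# Kendall's W with tie correction, straight from the definition
oracle_kendalls_w <- function(x) {
  m <- nrow(x); n <- ncol(x)
  rk <- t(apply(x, 1, rank))
  S <- 0
  for (j in seq_len(n)) S <- S + (sum(rk[, j]) - m * (n + 1) / 2)^2
  Tsum <- 0
  for (i in seq_len(m)) {
    for (t in table(x[i, ])) Tsum <- Tsum + (t^3 - t)
  }
  12 * S / (m^2 * (n^3 - n) - m * Tsum)
}

# AHM: conversion + scaled row sums, loop form
oracle_ahm <- function(b, beta) {
  n <- nrow(b)
  u <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    k <- b[i, j]
    u[i, j] <- if (k > 1) beta * k / (beta * k + 1)
               else if (k == 1) 0.5
               else {
        kk <- b[j, i]
        1 / (beta * kk + 1)
      }
  }
  w <- numeric(n)
  for (i in 1:n) w[i] <- 2 / (n * (n - 1)) * sum(u[i, ])
  w
}

# grey evaluation coefficients for one rating vector under a scheme, loop form
oracle_grey_r <- function(x, scheme) {
  K <- length(scheme$classes)
  n_e <- numeric(K)
  for (e in seq_len(K)) {
    f <- scheme$functions[[e]]
    for (xi in x) n_e[e] <- n_e[e] + whitening_value(f, xi, scheme$axis)
  }
  n_e / sum(n_e)
}

# grey relational grades, loop form
oracle_gra <- function(x, weights, rho, ref = 5) {
  delta <- abs(ref - x)
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) return(rep(1, nrow(x)))
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    g <- 0
    for (k in seq_len(ncol(x)))
      g <- g + weights[k] * (dmin + rho * dmax) / (delta[i, k] + rho * dmax)
    out[i] <- g / sum(weights)
  }
  out
}

# a random positive reciprocal matrix with entries on the Saaty lattice
random_saaty_matrix <- function(n) {
  lattice <- c(1 / (9:2), 1:9)
  b <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- sample(lattice, 1)
    b[i, j] <- v; b[j, i] <- 1 / v
  }
  comparison_matrix(b)
}

# minimal 3-level toy trees
toy_chain_tree <- function() {
  indicator_tree(data.frame(
    id = c("a", "a1", "a11"), parent_id = c(NA, "a", "a1"),
    level = 1:3, weight = c(1, 1, 1)))
}

toy_balanced_tree <- function() {
  indicator_tree(data.frame(
    id        = c("a", "b", "a1", "a2", "b1", "a11", "a12", "a21", "b11", "b12"),
    parent_id = c(NA, NA, "a", "a", "b", "a1", "a1", "a2", "b1", "b1"),
    level     = c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3),
    weight    = c(0.6, 0.4, 0.7, 0.3, 1, 0.5, 0.5, 1, 0.25, 0.75)))
}

# response table with fixed ratings over a tree's leaves
fixed_responses <- function(tree, ratings) {
  leaves <- leaf_ids(tree)
  m <- matrix(ratings, nrow = if (is.matrix(ratings)) nrow(ratings) else 1,
              ncol = length(leaves),
              dimnames = list(NULL, leaves))
  df <- data.frame(respondent_id = paste0("r", seq_len(nrow(m))))
  response_table(cbind(df, as.data.frame(m)), leaf_ids = leaves)
}

# scheme whose middle classes are triangular, so only the top class is
# positive at the top rating (composite can attain the max grade value)
triangular_scheme <- function() {
  grey_scheme(
    classes = c("excellent", "good", "medium", "poor"),
    functions = list(
      whitening_function("upper_limit", c(4, 5)),
      whitening_function("triangular", c(2.5, 4, 5)),
      whitening_function("triangular", c(1, 2.5, 4)),
      whitening_function("lower_limit", c(1, 2.5))
    ),
    grade_values = c(1.0, 0.8, 0.6, 0.4))
}
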