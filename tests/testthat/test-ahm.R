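test_that("attribute-measure conversion follows the defining formula", {
  m <- comparison_matrix(rbind(c(1, 3), c(1/3, 1)))
  u <- to_attribute_measure(m, beta = 2)$u
  expect_equal(u[1, 2], 6 / 7)
  expect_equal(u[2, 1], 1 / 7)
  expect_equal(diag(u), c(item1 = 0, item2 = 0))
  # indifference: all-ones matrix
  u3 <- to_attribute_measure(comparison_matrix(matrix(1, 3, 3)), beta = 2)$u
  expect_equal(diag(u3), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(u3[row(u3) != col(u3)] == 0.5))
  # pair-sum identity on random matrices, both beta regimes
  set.seed(3)
  for (beta in c(1, 2)) for (rep in 1:10) {
    mm <- random_saaty_matrix(sample(3:7, 1))
    uu <- to_attribute_measure(mm, beta)$u
    n <- nrow(uu)
    expect_equal(uu + t(uu), matrix(1, n, n) - diag(n),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("AHM weights match the brute-force row-sum oracle and normalize", {
  m <- comparison_matrix(rbind(c(1, 3), c(1/3, 1)))
  expect_equal(unname(ahm_weights(m, beta = 2)), c(6 / 7, 1 / 7))
  expect_equal(unname(ahm_weights(comparison_matrix(matrix(1, 3, 3)))),
               rep(1 / 3, 3))
  set.seed(4)
  for (rep in 1:25) {
    mm <- random_saaty_matrix(sample(2:8, 1))
    w <- ahm_weights(mm, beta = 2)
    expect_equal(unname(w), oracle_ahm(mm$b, 2), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("AHM weights are permutation-equivariant and dominance-monotone", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    mm <- random_saaty_matrix(n)
    w <- ahm_weights(mm)
    p <- sample(n)
    wp <- ahm_weights(comparison_matrix(mm$b[p, p],
                                        item_ids = mm$item_ids[p]))
    expect_equal(unname(wp), unname(w[p]), tolerance = 1e-12)
    # raising b[i, j] never decreases w[i]
    i <- 1; j <- 2
    b2 <- mm$b
    b2[i, j] <- min(9, b2[i, j] * 2); b2[j, i] <- 1 / b2[i, j]
    w2 <- ahm_weights(suppressWarnings(comparison_matrix(b2)))
    expect_gte(w2[i], w[i] - 1e-12)
  }
})

test_that("AHP eigenvector recovers consistent matrices and agrees with eigen()", {
  w_true <- c(0.5, 0.3, 0.2)
  b <- outer(w_true, w_true, `/`)
  res <- suppressWarnings(ahp_eigen_weights(comparison_matrix(b)))
  expect_equal(unname(res$weights), w_true, tolerance = 1e-10)
  expect_equal(res$CR, 0, tolerance = 1e-10)
  expect_equal(res$lambda_max, 3, tolerance = 1e-10)
  # all-ones: uniform weights, lambda = n, CR = 0
  res1 <- ahp_eigen_weights(comparison_matrix(matrix(1, 4, 4)))
  expect_equal(unname(res1$weights), rep(0.25, 4))
  expect_equal(res1$CR, 0, tolerance = 1e-12)
  # random reciprocal matrices: agree with the dense eigensolver oracle
  set.seed(6)
  for (rep in 1:10) {
    mm <- random_saaty_matrix(4)
    res <- ahp_eigen_weights(mm)
    ev <- eigen(mm$b)
    k <- which.max(Re(ev$values))
    v <- abs(Re(ev$vectors[, k]))
    expect_equal(unname(res$weights), v / sum(v), tolerance = 1e-8)
    expect_equal(res$lambda_max, max(Re(ev$values)), tolerance = 1e-8)
  }
})

test_that("AHM and AHP agree on the ranking in the consistent limit", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    w_true <- as.vector(stats::rgamma(n, 2)); w_true <- w_true / sum(w_true)
    b <- outer(w_true, w_true, `/`)
    m <- suppressWarnings(comparison_matrix(b))
    expect_equal(unname(ahp_eigen_weights(m)$weights), w_true,
                 tolerance = 1e-9)
    expect_identical(order(ahm_weights(m)), order(w_true))
  }
})

test_that("expert aggregation pools by element-wise geometric mean", {
  m1 <- comparison_matrix(rbind(c(1, 2), c(1/2, 1)))
  m8 <- comparison_matrix(rbind(c(1, 8), c(1/8, 1)))
  agg <- aggregate_experts(list(m1, m8))
  expect_equal(agg$b[1, 2], 4)
  # single matrix aggregates to itself
  expect_equal(aggregate_experts(list(m8))$b, m8$b)
  # a matrix and its element-wise reciprocal cancel to all ones
  minv <- comparison_matrix(1 / m8$b)
  expect_equal(aggregate_experts(list(m8, minv))$b,
               matrix(1, 2, 2), ignore_attr = TRUE)
  # mismatched item sets refuse to pool
  m_other <- comparison_matrix(rbind(c(1, 2), c(1/2, 1)),
                               item_ids = c("p", "q"))
  expect_error(aggregate_experts(list(m1, m_other)), "share item_ids")
})

test_that("weight_tree recovers planted weights from consistent matrices", {
  tree <- toy_balanced_tree()
  groups <- tree_sibling_groups(tree)
  matrices <- lapply(groups, function(w) {
    if (length(w) < 2) return(NULL)
    # noise-free, unquantized ratio matrices: AHM ranking matches, and with
    # per-pair conversion the planted weights come back through re-derivation
    list(suppressWarnings(comparison_matrix(outer(w, w, `/`),
                                            item_ids = names(w))))
  })
  matrices <- matrices[!vapply(matrices, is.null, TRUE)]
  tree2 <- weight_tree(tree, matrices, beta = 2)
  # sibling sums exactly 1
  for (g in tree_sibling_groups(tree2)) expect_equal(sum(g), 1, tolerance = 1e-12)
  # ranking within every group preserved
  for (p in names(groups)) {
    if (length(groups[[p]]) < 2) next
    expect_identical(order(tree_sibling_groups(tree2)[[p]]),
                     order(groups[[p]]))
  }
  # chain tree needs no matrices at all: single-child groups get weight 1
  chain <- weight_tree(toy_chain_tree(), list())
  expect_true(all(chain$weight == 1))
  # missing sibling group is an error naming the node
  expect_error(weight_tree(tree, matrices[-1]), "sibling group under")
})

test_that("re-deriving the packaged scale through Saaty quantization stays close", {
  tree <- resilience_scale()
  spec <- panel_spec(tree_sibling_groups(tree), n_experts = 1,
                     judgment_noise_sd = 0, seed = 1)
  tree2 <- weight_tree(tree, simulate_panel(spec), beta = 2)
  err <- abs(tree2$weight - tree$weight)
  expect_lte(mean(err), 0.05)
})
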