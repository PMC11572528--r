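test_that("whitening functions hit their piecewise-linear anchors", {
  up <- whitening_function("upper_limit", c(4, 5))
  expect_equal(whitening_value(up, c(4, 4.5, 5)), c(0, 0.5, 1))
  lo <- whitening_function("lower_limit", c(1, 2))
  expect_equal(whitening_value(lo, c(1, 1.5, 2)), c(1, 0.5, 0))
  tri <- whitening_function("triangular", c(1, 3, 5))
  expect_equal(whitening_value(tri, c(1, 2, 3, 4, 5)), c(0, 0.5, 1, 0.5, 0))
  mod <- whitening_function("moderate", c(1, 2, 3, 5))
  expect_equal(whitening_value(mod, c(1, 1.5, 2.5, 4, 5)), c(0, 0.5, 1, 0.5, 0))
  expect_error(whitening_value(up, 7), "outside")
  expect_error(whitening_function("upper_limit", c(3, 3)), "strictly increasing")
})

test_that("whitening values stay in [0,1] with the right monotone form", {
  set.seed(10)
  grid <- seq(1, 5, by = 0.05)
  for (rep in 1:30) {
    bp <- sort(stats::runif(2, 1, 5))
    while (diff(bp) < 0.1) bp <- sort(stats::runif(2, 1, 5))
    up <- whitening_value(whitening_function("upper_limit", bp), grid)
    lo <- whitening_value(whitening_function("lower_limit", bp), grid)
    expect_true(all(up >= 0 & up <= 1 & lo >= 0 & lo <= 1))
    expect_true(all(diff(up) >= 0))   # upper limit: non-decreasing
    expect_true(all(diff(lo) <= 0))   # lower limit: non-increasing
  }
})

test_that("grey evaluation coefficients sum to 1 and match the oracle", {
  tree <- toy_chain_tree()
  scheme <- default_grey_scheme()
  # all respondents give the top rating: r maximal on "excellent"
  rt <- fixed_responses(tree, matrix(5, nrow = 10))
  r <- grey_coefficients(rt, scheme, "a11")
  expect_equal(sum(r$r_e), 1)
  expect_true(all(r$r_e["excellent"] >= r$r_e))
  expect_equal(unname(r$r_e[["poor"]]), 0)
  # brute-force oracle over a random cohort
  set.seed(12)
  x <- sample(1:5, 100, replace = TRUE)
  rt2 <- fixed_responses(tree, matrix(x, ncol = 1))
  r2 <- grey_coefficients(rt2, scheme, "a11")
  expect_equal(unname(r2$r_e), oracle_grey_r(x, scheme), tolerance = 1e-12)
  # a custom scheme that misses part of the axis flags the leaf degenerate
  narrow <- grey_scheme(
    classes = c("hi", "lo"),
    functions = list(whitening_function("upper_limit", c(4, 5)),
                     whitening_function("lower_limit", c(1, 2))),
    grade_values = c(1, 0.4))
  r3 <- grey_coefficients(fixed_responses(tree, matrix(3, nrow = 5)),
                          narrow, "a11")
  expect_true(r3$degenerate)
})

test_that("cluster aggregation normalizes, respects weights, and is exact on anchors", {
  tree <- toy_balanced_tree()
  scheme <- default_grey_scheme()
  set.seed(13)
  rt <- fixed_responses(tree, matrix(sample(1:5, 20 * 5, replace = TRUE),
                                     nrow = 20))
  fit <- grey_eval(rt, tree, scheme)
  rcols <- paste0("r_", scheme$classes)
  for (i in seq_len(nrow(fit$nodes)))
    expect_equal(sum(fit$nodes[i, rcols]), 1, tolerance = 1e-9)
  # composite bounded by the grade values
  expect_true(all(fit$nodes$composite >= min(scheme$grade_values) - 1e-12))
  expect_true(all(fit$nodes$composite <= max(scheme$grade_values) + 1e-12))
  # single-leaf chain: every level repeats the leaf score
  chain_fit <- grey_eval(fixed_responses(toy_chain_tree(),
                                         matrix(sample(1:5, 15, TRUE))),
                         toy_chain_tree(), scheme)
  expect_equal(length(unique(round(chain_fit$nodes$composite, 12))), 1L)
  # identical leaf r-vectors: every node inherits the common vector
  rt_same <- fixed_responses(tree, matrix(rep(c(2, 4, 4, 5, 3), 5), nrow = 5))
  # (every leaf column carries the same rating multiset)
  fit_same <- grey_eval(rt_same, tree, scheme)
  for (i in seq_len(nrow(fit_same$nodes)))
    expect_equal(unlist(fit_same$nodes[i, rcols]),
                 unlist(fit_same$nodes[1, rcols]), tolerance = 1e-9)
})

test_that("top-rating cohorts attain the scheme's exact upper bound", {
  tree <- toy_balanced_tree()
  # default scheme (three upper-limit + one lower-limit classes): the bound is
  # the normalized top-rating membership dotted with the grades
  scheme <- default_grey_scheme()
  rt <- fixed_responses(tree, matrix(5, nrow = 8))
  fit <- grey_eval(rt, tree, scheme)
  m_top <- vapply(scheme$functions, whitening_value, 0, x = 5)
  bound <- sum(m_top / sum(m_top) * scheme$grade_values)
  expect_equal(fit$overall, bound, tolerance = 1e-12)
  expect_equal(unique(round(fit$nodes$composite, 12)), round(bound, 12))
  # with triangular middle classes the top class is alone at the top rating
  # and the composite attains the maximum grade value exactly
  fit_tri <- grey_eval(rt, tree, triangular_scheme())
  expect_equal(fit_tri$overall, 1)
})

test_that("composite score is monotone in any single rating", {
  tree <- toy_balanced_tree()
  scheme <- default_grey_scheme()
  set.seed(14)
  base <- matrix(sample(1:5, 6 * 5, replace = TRUE), nrow = 6)
  fit0 <- grey_eval(fixed_responses(tree, base), tree, scheme)
  for (rep in 1:15) {
    i <- sample(6, 1); j <- sample(5, 1)
    if (base[i, j] == 5) next
    up <- base; up[i, j] <- up[i, j] + 1
    fit1 <- grey_eval(fixed_responses(tree, up), tree, scheme)
    expect_true(all(fit1$nodes$composite >= fit0$nodes$composite - 1e-9))
  }
  # and pointwise on the whole axis for a single respondent
  grid <- seq(1, 5, by = 0.1)
  m <- vapply(scheme$functions, whitening_value, numeric(length(grid)),
              x = grid)
  g <- as.vector((m / rowSums(m)) %*% scheme$grade_values)
  expect_true(all(diff(g) >= -1e-12))
})

test_that("per-respondent medians track a planted group difference", {
  tree <- resilience_scale()
  spec_hi <- cohort_spec(n_respondents = 80, seed = 21,
                         group_effects = list(exercise_habit = c(stable = 1.5)))
  rt <- simulate_cohort(spec_hi, tree)
  fit <- grey_eval(rt, tree)
  sc <- fit$respondent_scores[, "overall"]
  hab <- rt$meta_exercise_habit
  expect_gt(stats::median(sc[hab == "stable"]),
            stats::median(sc[hab == "none"]))
})

test_that("grey relational grades match the brute-force oracle and anchors", {
  tree <- toy_balanced_tree()
  set.seed(15)
  x <- matrix(sample(1:5, 50 * 5, replace = TRUE), nrow = 50)
  x[1, ] <- 5                       # respondent identical to the reference
  rt <- fixed_responses(tree, x)
  g <- grey_relational_score(rt, tree, rho = 0.5)
  expect_equal(unname(g[1]), 1)
  w <- global_leaf_weights(tree)[leaf_ids(tree)]
  expect_equal(unname(g), oracle_gra(x, w / sum(w), 0.5), tolerance = 1e-12)
  # constant table: all grades 1 by the degenerate rule
  g1 <- grey_relational_score(fixed_responses(tree, matrix(4, nrow = 3)),
                              tree, rho = 0.5)
  expect_equal(unname(g1), rep(1, 3))
  # permuting leaves together with their weights leaves the grades unchanged
  perm <- sample(leaf_ids(tree))
  df <- as.data.frame(rt)[, c("respondent_id", perm)]
  rt_p <- response_table(df, leaf_ids = perm)
  expect_equal(unname(grey_relational_score(rt_p, tree, 0.5)), unname(g),
               tolerance = 1e-12)
  expect_error(grey_relational_score(rt, tree, rho = 0), "rho")
})

test_that("grey scheme YAML round-trips through the loader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  s <- default_grey_scheme()
  yaml::write_yaml(list(
    axis = s$axis,
    classes = lapply(s$classes, function(cl) list(
      name = cl, form = s$functions[[cl]]$form,
      breakpoints = s$functions[[cl]]$breakpoints,
      grade = unname(s$grade_values[cl])))), f)
  s2 <- load_grey_scheme(f)
  expect_equal(s2$classes, s$classes)
  expect_equal(s2$grade_values, s$grade_values)
  expect_equal(s2$functions[["good"]]$breakpoints,
               s$functions[["good"]]$breakpoints)
})
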