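test_that("Kendall's W hits the textbook anchors", {
  # identical rankings -> perfect concordance
  r <- delphi_round(matrix(rep(c(2, 4, 1, 3), 3), nrow = 3, byrow = TRUE))
  expect_equal(kendalls_w(r)$W, 1)
  # two reversed rankings -> equal rank sums, W = 0
  r0 <- delphi_round(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(kendalls_w(r0)$W, 0)
  # all-tied ratings -> degenerate flag, no crash
  rd <- delphi_round(matrix(3, 4, 5))
  wd <- kendalls_w(rd)
  expect_true(wd$degenerate)
  expect_true(is.na(wd$W))
})

test_that("W matches the independent defining-formula oracle and friedman.test", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(3:8, 1); n <- sample(4:10, 1)
    x <- matrix(sample(1:5, m * n, replace = TRUE), m, n)
    if (any(apply(x, 1, function(r) length(unique(r))) == 1)) next
    res <- kendalls_w(delphi_round(x))
    expect_equal(res$W, oracle_kendalls_w(x), tolerance = 1e-12)
    # dual route: tie-corrected Friedman chi-square = m (n-1) W
    fr <- stats::friedman.test(x)
    expect_equal(res$chi2, unname(fr$statistic), tolerance = 1e-10)
    expect_equal(res$p, fr$p.value, tolerance = 1e-10)
  }
})

test_that("W is invariant to relabeling, bounded, and tie-consistent", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(3:8, 1); n <- sample(3:9, 1)
    x <- matrix(sample(1:5, m * n, replace = TRUE), m, n)
    w <- kendalls_w(delphi_round(x))$W
    if (is.na(w)) next
    expect_gte(w, 0); expect_lte(w, 1)
    # permuting experts and items leaves W unchanged
    wp <- kendalls_w(delphi_round(x[sample(m), sample(n)]))$W
    expect_equal(w, wp, tolerance = 1e-12)
    # duplicating the whole panel leaves W unchanged
    wd <- kendalls_w(delphi_round(rbind(x, x)))$W
    expect_equal(wd, w, tolerance = 1e-12)
  }
  # untied data: tie-corrected W equals the uncorrected formula
  set.seed(8)
  x <- t(replicate(5, sample(1:7)))
  S <- sum((colSums(t(apply(x, 1, rank))) - 5 * 8 / 2)^2)
  expect_equal(kendalls_w(delphi_round(x))$W, 12 * S / (25 * (7^3 - 7)))
})

test_that("permutation p-value agrees with the chi-square approximation", {
  set.seed(11)
  x <- matrix(sample(1:5, 6 * 8, replace = TRUE), 6, 8)
  res <- kendalls_w(delphi_round(x), exact = TRUE, n_perm = 4000)
  expect_true(abs(res$p_perm - res$p) < 0.1)
})

test_that("screening keeps high-mean low-CV items and reports audit stats", {
  x <- cbind(A = rep(5, 6), B = rep(1, 6))
  x[1, "B"] <- 2   # break the all-tied degenerate case
  r <- delphi_round(x)
  res <- screen_indicators(r, screening_rule(3.5, 0.25))
  expect_identical(res$kept, "A")
  expect_identical(res$dropped, "B")
  expect_equal(res$per_item$mean[1], 5)
  # vacuous rule keeps everything
  res2 <- screen_indicators(r, screening_rule(min(x), Inf))
  expect_length(res2$dropped, 0)
  # a rule nothing satisfies warns about the empty keep-set
  expect_warning(screen_indicators(r, screening_rule(5.1, 0.01)), "no indicators")
})

test_that("planted screening round recovers exactly its keep-set", {
  sim <- simulate_screening_round(n_experts = 25, n_items = 116, n_keep = 46,
                                  rule = screening_rule(), seed = 5)
  res <- screen_indicators(sim$round, screening_rule())
  expect_identical(sort(res$kept), sim$keep)
  expect_length(res$kept, 46L)
  expect_length(res$dropped, 70L)
})

test_that("expert-ratings CSV loads as a round", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(expert_id = c("e1", "e2", "e3"),
                              i1 = c(5, 4, 5), i2 = c(2, 1, 2)),
                   f, row.names = FALSE)
  r <- load_delphi_round(f, round = 2)
  expect_identical(r$item_ids, c("i1", "i2"))
  expect_identical(dim(r$ratings), c(3L, 2L))
  expect_identical(r$round, 2L)
})
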