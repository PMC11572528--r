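#' Rank-based comparison of scores across covariate groups
#'
#' Compares per-respondent composite scores between the levels of a covariate
#' using the tests conventional for median (QR)-style reporting: the Wilcoxon
#' rank-sum test for two groups, the Kruskal-Wallis rank test for more, and
#' pairwise rank-sum post-hoc tests with multiplicity adjustment (Bonferroni
#' by default). Ties are handled by average ranks with the normal
#' approximation correction of the underlying \pkg{stats} tests.
#'
#' @param scores Numeric vector of per-respondent scores, aligned with the
#'   rows of `table` (e.g. a column of `grey_eval()$respondent_scores` or
#'   [grey_relational_score] output).
#' @param table The [response_table] carrying the covariates.
#' @param factor Covariate name (with or without the `meta_` prefix).
#' @param adjust Multiplicity adjustment for pairwise tests; any
#'   [stats::p.adjust] method.
#' @param min_group_size Groups smaller than this are excluded from pairwise
#'   testing (noted in the result), default 2.
#' @return Object of class `group_comparison`: the omnibus `method`,
#'   `statistic` and `p.value`, per-group `n`/`median`/`iqr`, a `pairwise`
#'   data frame with raw and adjusted p-values, and `small_groups` skipped in
#'   pairwise testing.
#' @export
compare_by_factor <- function(scores, table, factor,
                              adjust = "bonferroni", min_group_size = 2L) {
  stopifnot(inherits(table, "response_table"))
  col <- if (factor %in% names(table)) factor else paste0("meta_", factor)
  if (!(col %in% names(table))) stop("covariate '", factor, "' not found")
  if (length(scores) != nrow(table))
    stop("scores length does not match the number of respondents")
  g <- as.factor(table[[col]])
  ok <- !is.na(scores) & !is.na(g)
  scores <- scores[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups for '", factor, "'")
  group_stats <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    median = as.numeric(tapply(scores, g, stats::median)),
    iqr = as.numeric(tapply(scores, g, stats::IQR)),
    row.names = NULL)
  if (nlevels(g) == 2L) {
    ht <- suppressWarnings(stats::wilcox.test(scores ~ g))
    method <- "Wilcoxon rank-sum"
  } else {
    ht <- stats::kruskal.test(scores ~ g)
    method <- "Kruskal-Wallis"
  }
  big <- levels(g)[table(g) >= min_group_size]
  small <- setdiff(levels(g), big)
  pairwise <- NULL
  if (length(big) >= 2L) {
    pairs <- utils::combn(big, 2L)
    praw <- apply(pairs, 2L, function(pr) {
      suppressWarnings(stats::wilcox.test(
        scores[g == pr[1L]], scores[g == pr[2L]]))$p.value
    })
    pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                           p = praw,
                           p_adjusted = pmax(stats::p.adjust(praw, adjust), praw),
                           row.names = NULL)
  }
  structure(list(factor = factor, method = method,
                 statistic = unname(ht$statistic), p.value = ht$p.value,
                 groups = group_stats, pairwise = pairwise,
                 small_groups = small, adjust = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison by '%s' (%s): statistic = %.3f, p = %.4g\n",
              x$factor, x$method, x$statistic, x$p.value))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat(sprintf("Pairwise rank-sum tests (%s-adjusted):\n", x$adjust))
    print(x$pairwise, row.names = FALSE)
  }
  if (length(x$small_groups))
    cat("Excluded from pairwise testing (too small):",
        paste(x$small_groups, collapse = ", "), "\n")
  invisible(x)
}
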