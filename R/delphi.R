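#' Expert rating rounds
#'
#' Container for one Delphi consultation round: an experts-by-items matrix of
#' ordinal importance ratings (e.g. 1-5).
#'
#' @param ratings Numeric matrix, experts in rows, items in columns. At least
#'   2 experts and 2 items.
#' @param item_ids Optional item labels (default: column names or `item1..n`).
#' @param round Round number (integer >= 1).
#' @return An object of class `delphi_round`.
#' @export
delphi_round <- function(ratings, item_ids = NULL, round = 1L) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L || ncol(ratings) < 2L)
    stop("a Delphi round needs at least 2 experts and 2 items")
  if (anyNA(ratings)) stop("ratings must not contain missing values")
  if (is.null(item_ids))
    item_ids <- if (!is.null(colnames(ratings))) colnames(ratings)
                else paste0("item", seq_len(ncol(ratings)))
  if (length(item_ids) != ncol(ratings))
    stop("item_ids length does not match the number of items")
  colnames(ratings) <- item_ids
  structure(list(round = as.integer(round), ratings = ratings,
                 item_ids = as.character(item_ids)),
            class = "delphi_round")
}

#' Kendall's coefficient of concordance with tie correction
#'
#' Agreement among m experts over n items, computed on within-expert ranks
#' (average ranks for ties):
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum T},\quad
#'       S = \sum_i \left(R_i - \frac{m(n+1)}{2}\right)^2,}
#' where \eqn{R_i} are item rank sums and \eqn{T = \sum (t^3 - t)} over each
#' expert's tie groups. Significance uses the chi-square approximation
#' \eqn{\chi^2 = m (n - 1) W} with \eqn{n - 1} degrees of freedom; for small
#' problems an exact permutation p-value over all expert rankings is available
#' as a cross-check.
#'
#' @param round A [delphi_round] (or a bare experts-by-items matrix).
#' @param exact If `TRUE` and the problem is small (n <= 10 items is
#'   practical), also compute a Monte-Carlo-free exact permutation p-value by
#'   enumerating... (for m > 2 full enumeration explodes, so the exact p is
#'   computed by within-expert rank permutation Monte Carlo with `n_perm`
#'   draws).
#' @param n_perm Permutation draws for the resampling p-value.
#' @return List of class `kendall_w` with elements `W` (in \[0, 1\], `NA` with
#'   `degenerate = TRUE` when every expert ties all items), `chi2`, `df`, `p`,
#'   `n_experts`, `n_items`, and `p_perm` when requested.
#' @examples
#' r <- delphi_round(rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4)))
#' kendalls_w(r)$W  # 1: perfect concordance
#' @export
kendalls_w <- function(round, exact = FALSE, n_perm = 2000L) {
  if (!inherits(round, "delphi_round")) round <- delphi_round(round)
  x <- round$ratings
  m <- nrow(x); n <- ncol(x)
  rk <- t(apply(x, 1L, rank))          # within-expert average ranks
  Tm <- apply(x, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  })
  R <- colSums(rk)
  S <- sum((R - m * (n + 1) / 2)^2)
  denom <- m^2 * (n^3 - n) - m * sum(Tm)
  if (denom <= 0) {                    # all items tied within every expert
    out <- list(W = NA_real_, chi2 = NA_real_, df = n - 1L, p = NA_real_,
                degenerate = TRUE, n_experts = m, n_items = n)
    class(out) <- "kendall_w"
    return(out)
  }
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  p <- stats::pchisq(chi2, df = n - 1, lower.tail = FALSE)
  out <- list(W = W, chi2 = chi2, df = n - 1L, p = p, degenerate = FALSE,
              n_experts = m, n_items = n)
  if (exact) {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      rkp <- t(apply(rk, 1L, sample))
      Rp <- colSums(rkp)
      Sp <- sum((Rp - m * (n + 1) / 2)^2)
      if (Sp >= S - 1e-12) ge <- ge + 1L
    }
    out$p_perm <- (ge + 1) / (n_perm + 1)
  }
  class(out) <- "kendall_w"
  out
}

#' @export
print.kendall_w <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Kendall's W: undefined (all items tied within every expert)\n")
  } else {
    cat(sprintf("Kendall's W = %.4f (m = %d experts, n = %d items)\n",
                x$W, x$n_experts, x$n_items))
    cat(sprintf("  chi-square = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
    if (!is.null(x$p_perm))
      cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  }
  invisible(x)
}

#' Screening rule for Delphi indicator selection
#'
#' An indicator survives a round when its mean importance is at least
#' `min_mean_importance` and its coefficient of variation (sd/mean) is at most
#' `max_cv`. The published funnel (116 candidate items screened down to 46)
#' never states its thresholds; the defaults, mean >= 3.5 and CV <= 0.25, are
#' common Delphi practice and fully configurable.
#'
#' @param min_mean_importance Minimum mean rating to keep an item.
#' @param max_cv Maximum coefficient of variation (must be > 0).
#' @return Object of class `screening_rule`.
#' @export
screening_rule <- function(min_mean_importance = 3.5, max_cv = 0.25) {
  if (!is.finite(min_mean_importance))
    stop("min_mean_importance must be finite")
  if (!(max_cv > 0)) stop("max_cv must be > 0")
  structure(list(min_mean_importance = min_mean_importance, max_cv = max_cv),
            class = "screening_rule")
}

#' Screen indicators after a Delphi round
#'
#' @param round A [delphi_round].
#' @param rule A [screening_rule].
#' @return List with `kept` and `dropped` item-id vectors and a `per_item`
#'   data frame (mean, sd, cv) for audit. An empty keep-set is allowed but
#'   raised as a warning.
#' @export
screen_indicators <- function(round, rule = screening_rule()) {
  stopifnot(inherits(round, "delphi_round"), inherits(rule, "screening_rule"))
  x <- round$ratings
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdv / mu)
  keep <- mu >= rule$min_mean_importance & cv <= rule$max_cv
  if (!any(keep)) warning("screening rule kept no indicators")
  list(kept = round$item_ids[keep],
       dropped = round$item_ids[!keep],
       per_item = data.frame(item = round$item_ids, mean = mu, sd = sdv,
                             cv = cv, kept = keep, row.names = NULL))
}

#' Read an expert-ratings CSV (rows = experts, columns = item ids)
#'
#' @param path CSV path; an optional `expert_id` column is dropped.
#' @param round Round number attached to the result.
#' @return A [delphi_round].
#' @export
load_delphi_round <- function(path, round = 1L) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$expert_id <- NULL
  delphi_round(as.matrix(df), round = round)
}
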