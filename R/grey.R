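#' Whitening weight functions
#'
#' Piecewise-linear membership functions mapping a rating to its degree of
#' belonging to a grey class. Four forms are supported on a rating axis
#' `[axis_min, axis_max]`:
#' \describe{
#'   \item{`upper_limit`, breakpoints (a, b)}{0 for x <= a, linear ramp on
#'     (a, b), 1 for x >= b.}
#'   \item{`lower_limit`, breakpoints (a, b)}{1 for x <= a, linear descent on
#'     (a, b), 0 for x >= b.}
#'   \item{`triangular`, breakpoints (a, b, c)}{0 outside (a, c), rising to 1
#'     at the peak b.}
#'   \item{`moderate`, breakpoints (a, b, c, d)}{trapezoid: rises on (a, b),
#'     flat 1 on \[b, c\], falls on (c, d).}
#' }
#'
#' @param form One of `"upper_limit"`, `"lower_limit"`, `"triangular"`,
#'   `"moderate"`.
#' @param breakpoints Strictly increasing turning points on the rating axis.
#' @return Object of class `whitening_function`.
#' @export
whitening_function <- function(form = c("upper_limit", "lower_limit",
                                        "triangular", "moderate"),
                               breakpoints) {
  form <- match.arg(form)
  breakpoints <- as.numeric(breakpoints)
  need <- c(upper_limit = 2L, lower_limit = 2L, triangular = 3L, moderate = 4L)
  if (length(breakpoints) != need[[form]])
    stop(sprintf("form '%s' needs %d breakpoints", form, need[[form]]))
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  structure(list(form = form, breakpoints = breakpoints),
            class = "whitening_function")
}

#' Evaluate a whitening weight function
#'
#' @param f A [whitening_function].
#' @param x Ratings (vectorized).
#' @param axis Rating axis `c(min, max)`; values outside it are an error.
#' @return Membership values in \[0, 1\].
#' @examples
#' f <- whitening_function("upper_limit", c(4, 5))
#' whitening_value(f, c(4, 4.5, 5))  # 0, 0.5, 1
#' @export
whitening_value <- function(f, x, axis = c(1, 5)) {
  stopifnot(inherits(f, "whitening_function"))
  if (any(!is.na(x) & (x < axis[1] | x > axis[2])))
    stop(sprintf("rating outside the [%g, %g] axis", axis[1], axis[2]))
  b <- f$breakpoints
  ramp_up   <- function(x, a, b) pmin(1, pmax(0, (x - a) / (b - a)))
  ramp_down <- function(x, a, b) pmin(1, pmax(0, (b - x) / (b - a)))
  switch(f$form,
    upper_limit = ramp_up(x, b[1], b[2]),
    lower_limit = ramp_down(x, b[1], b[2]),
    triangular  = pmin(ramp_up(x, b[1], b[2]), ramp_down(x, b[2], b[3])),
    moderate    = pmin(ramp_up(x, b[1], b[2]), ramp_down(x, b[3], b[4]))
  )
}

#' Grey evaluation schemes
#'
#' A scheme is an ordered set of grey classes, one whitening weight function
#' per class, and a grade value (score) attached to each class. The default
#' follows the published model's structure — four classes "excellent", "good",
#' "medium", "poor" realised by three upper-limit and one lower-limit
#' function — with reconstructed breakpoints (the published turning points are
#' not printed) chosen so that every rating on the 1-5 Likert axis has
#' positive total membership and the induced composite score is monotone in
#' the rating:
#' excellent = upper(4, 5), good = upper(2, 4), medium = upper(1, 3),
#' poor = lower(1, 5); grade values (1.0, 0.8, 0.6, 0.4).
#'
#' @param classes Ordered class labels, best first.
#' @param functions List of [whitening_function]s, one per class.
#' @param grade_values Strictly decreasing scores, one per class.
#' @param axis Rating axis `c(min, max)`.
#' @return Object of class `grey_scheme`.
#' @export
grey_scheme <- function(classes, functions, grade_values, axis = c(1, 5)) {
  stopifnot(length(classes) == length(functions),
            length(classes) == length(grade_values),
            all(vapply(functions, inherits, TRUE, "whitening_function")))
  if (any(diff(grade_values) >= 0))
    stop("grade_values must be strictly decreasing from the best class down")
  structure(list(classes = as.character(classes),
                 functions = stats::setNames(functions, classes),
                 grade_values = stats::setNames(as.numeric(grade_values), classes),
                 axis = as.numeric(axis)),
            class = "grey_scheme")
}

#' @rdname grey_scheme
#' @export
default_grey_scheme <- function() {
  grey_scheme(
    classes = c("excellent", "good", "medium", "poor"),
    functions = list(
      whitening_function("upper_limit", c(4, 5)),
      whitening_function("upper_limit", c(2, 4)),
      whitening_function("upper_limit", c(1, 3)),
      whitening_function("lower_limit", c(1, 5))
    ),
    grade_values = c(1.0, 0.8, 0.6, 0.4),
    axis = c(1, 5)
  )
}

#' Read a grey scheme from YAML
#'
#' Layout: top-level `axis: [min, max]` plus `classes:`, an ordered list of
#' mappings with keys `name`, `form`, `breakpoints`, `grade`.
#'
#' @param path YAML path.
#' @return A [grey_scheme].
#' @export
load_grey_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  cls <- y$classes
  grey_scheme(
    classes = vapply(cls, `[[`, "", "name"),
    functions = lapply(cls, function(cl)
      whitening_function(cl$form, as.numeric(cl$breakpoints))),
    grade_values = vapply(cls, function(cl) as.numeric(cl$grade), 0),
    axis = if (is.null(y$axis)) c(1, 5) else as.numeric(y$axis)
  )
}

# respondents x classes membership matrix for one vector of ratings
.memberships <- function(x, scheme) {
  vapply(scheme$functions, whitening_value, numeric(length(x)),
         x = x, axis = scheme$axis)
}

#' Grey evaluation coefficients for one leaf indicator
#'
#' For each grey class e the evaluation coefficient is the total whitening
#' membership over respondents, \eqn{n_e = \sum_i f_e(x_i)}, and the grey
#' evaluation weight is \eqn{r_e = n_e / N} with \eqn{N = \sum_e n_e}, so the
#' r-vector sums to 1. A leaf where N = 0 (possible only with custom schemes
#' that do not cover the axis) is flagged degenerate rather than an error.
#'
#' @param responses A [response_table].
#' @param scheme A [grey_scheme].
#' @param leaf Leaf indicator id.
#' @return List with `n_e`, `N`, `r_e` (named by class) and `degenerate`.
#' @export
grey_coefficients <- function(responses, scheme = default_grey_scheme(), leaf) {
  stopifnot(inherits(responses, "response_table"),
            inherits(scheme, "grey_scheme"))
  if (!(leaf %in% attr(responses, "leaf_ids")))
    stop("leaf '", leaf, "' not present in the response table")
  x <- responses[[leaf]]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing ratings for leaf '", leaf, "'")
  f <- .memberships(x, scheme)
  n_e <- colSums(f)
  N <- sum(n_e)
  r_e <- if (N > 0) n_e / N else stats::setNames(rep(NA_real_, length(n_e)),
                                                 names(n_e))
  list(n_e = n_e, N = N, r_e = r_e, degenerate = N == 0)
}

#' Fit the grey fixed-weight clustering evaluation model
#'
#' The central scoring model: per-leaf grey evaluation weight vectors (class
#' memberships pooled over respondents) are combined up the indicator tree —
#' an internal node's r-vector is the local-weight-weighted sum of its
#' children's r-vectors, renormalized — and each node's composite score is the
#' dot product of its r-vector with the scheme's grade values. Per-respondent
#' scores run the same recursion on each respondent's own within-leaf
#' normalized memberships, yielding the median and interquartile-range
#' summaries conventionally reported for such scales.
#'
#' @param responses A [response_table] whose leaf columns match `tree`.
#' @param tree An [indicator_tree].
#' @param scheme A [grey_scheme].
#' @return An object of class `grey_eval` with components:
#'   \item{nodes}{data frame: id, level, text, composite score, median, IQR
#'     over respondent scores, plus one `r_<class>` column per grey class.}
#'   \item{respondent_scores}{matrix respondents x (nodes + "overall").}
#'   \item{overall}{cohort-level composite score at the root.}
#'   \item{degenerate_leaves}{leaf ids with zero total membership, if any.}
#' @examples
#' tree <- resilience_scale()
#' rt <- simulate_cohort(cohort_spec(n_respondents = 50, seed = 1), tree)
#' fit <- grey_eval(rt, tree)
#' fit$overall
#' @export
grey_eval <- function(responses, tree, scheme = default_grey_scheme()) {
  stopifnot(inherits(responses, "response_table"),
            inherits(tree, "indicator_tree"), inherits(scheme, "grey_scheme"))
  leaves <- leaf_ids(tree)
  have <- attr(responses, "leaf_ids")
  if (!all(leaves %in% have))
    stop("response table lacks leaf column(s): ",
         paste(setdiff(leaves, have), collapse = ", "))
  K <- length(scheme$classes)
  n_resp <- nrow(responses)
  ids <- tree$id
  # pooled r-vector and per-respondent normalized memberships per leaf
  r_leaf <- matrix(NA_real_, length(leaves), K,
                   dimnames = list(leaves, scheme$classes))
  resp_leaf <- matrix(NA_real_, n_resp, length(leaves),
                      dimnames = list(NULL, leaves))
  degenerate <- character(0)
  for (lf in leaves) {
    x <- responses[[lf]]
    f <- .memberships(x, scheme)                 # n_resp x K
    tot_pool <- colSums(f, na.rm = TRUE)
    N <- sum(tot_pool)
    if (N == 0) { degenerate <- c(degenerate, lf); next }
    r_leaf[lf, ] <- tot_pool / N
    tot_i <- rowSums(f)
    ok <- !is.na(tot_i) & tot_i > 0
    resp_leaf[ok, lf] <- (f[ok, , drop = FALSE] / tot_i[ok]) %*%
      scheme$grade_values
  }
  # climb the tree: r-vectors and per-respondent scores
  r_node <- matrix(NA_real_, length(ids), K, dimnames = list(ids, scheme$classes))
  resp_node <- matrix(NA_real_, n_resp, length(ids), dimnames = list(NULL, ids))
  r_node[leaves, ] <- r_leaf
  resp_node[, leaves] <- resp_leaf
  combine <- function(kids) {
    w <- tree$weight[match(kids, ids)]
    rv <- colSums(w * r_node[kids, , drop = FALSE])
    rv <- rv / sum(rv)
    sc <- as.vector(resp_node[, kids, drop = FALSE] %*% w) / sum(w)
    list(rv = rv, sc = sc)
  }
  for (lv in c(2L, 1L)) for (id in ids[tree$level == lv]) {
    cb <- combine(.children(tree, id))
    r_node[id, ] <- cb$rv
    resp_node[, id] <- cb$sc
  }
  top <- ids[tree$level == 1L]
  cb <- combine(top)
  r_overall <- cb$rv
  resp_overall <- cb$sc
  composite <- as.vector(r_node %*% scheme$grade_values)
  med <- apply(resp_node, 2L, stats::median, na.rm = TRUE)
  iqr <- apply(resp_node, 2L, stats::IQR, na.rm = TRUE)
  nodes <- data.frame(id = ids, level = tree$level, text = tree$text,
                      composite = composite, median = med, iqr = iqr,
                      row.names = NULL)
  nodes <- cbind(nodes, stats::setNames(as.data.frame(r_node),
                                        paste0("r_", scheme$classes)))
  overall_row <- data.frame(id = "overall", level = 0L, text = "overall score",
                            composite = sum(r_overall * scheme$grade_values),
                            median = stats::median(resp_overall, na.rm = TRUE),
                            iqr = stats::IQR(resp_overall, na.rm = TRUE))
  overall_row <- cbind(overall_row,
                       stats::setNames(as.data.frame(t(r_overall)),
                                       paste0("r_", scheme$classes)))
  structure(list(nodes = rbind(overall_row, nodes),
                 respondent_scores = cbind(resp_node, overall = resp_overall),
                 overall = overall_row$composite,
                 degenerate_leaves = degenerate,
                 tree = tree, scheme = scheme, n_respondents = n_resp),
            class = "grey_eval")
}

#' @export
print.grey_eval <- function(x, ...) {
  cat(sprintf("Grey clustering evaluation: %d respondents, %d leaf indicators\n",
              x$n_respondents, sum(x$nodes$level == 3L)))
  cat(sprintf("Overall composite score: %.3f  [median %.3f (QR %.3f)]\n",
              x$overall, x$nodes$median[1L], x$nodes$iqr[1L]))
  if (length(x$degenerate_leaves))
    cat("Degenerate leaves (zero membership):",
        paste(x$degenerate_leaves, collapse = ", "), "\n")
  top <- x$nodes[x$nodes$level == 1L, ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-4s %.3f  median %.3f (QR %.3f)  %s\n", top$id[i],
                top$composite[i], top$median[i], top$iqr[i], top$text[i]))
  invisible(x)
}

#' @export
summary.grey_eval <- function(object, level = NULL, ...) {
  out <- object$nodes
  if (!is.null(level)) out <- out[out$level %in% level, ]
  out
}

#' @export
coef.grey_eval <- function(object, ...) {
  stats::setNames(object$nodes$composite, object$nodes$id)
}

#' Score new respondents against a fitted evaluation
#'
#' @param object A [grey_eval] fit.
#' @param newdata A [response_table] over the same leaves.
#' @param ... Unused.
#' @return Matrix of per-respondent node scores (plus `overall`).
#' @export
predict.grey_eval <- function(object, newdata, ...) {
  grey_eval(newdata, object$tree, object$scheme)$respondent_scores
}

#' @export
plot.grey_eval <- function(x, level = 2L, ...) {
  nd <- x$nodes[x$nodes$level == level, ]
  op <- graphics::par(mar = c(6, 4, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(stats::setNames(nd$composite, nd$id),
                    las = 2, ylim = c(0, 1),
                    ylab = "composite score",
                    main = sprintf("Grey composite scores (level %d)", level), ...)
  graphics::abline(h = x$overall, lty = 2)
  invisible(x)
}

#' Grey relational scores of respondents
#'
#' Grey relational analysis against the ideal respondent: the reference
#' series takes the maximal rating on every leaf; per leaf k and respondent i
#' the deviation is \eqn{\Delta_i(k) = |x_0(k) - x_i(k)|} and the relational
#' coefficient is
#' \deqn{\gamma_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                         {\Delta_i(k) + \rho\,\Delta_{max}}}
#' with global extrema over the whole table and distinguishing coefficient
#' rho. The relational grade is the global-leaf-weight-weighted mean,
#' \eqn{\Gamma_i = \sum_k w_k \gamma_i(k)}. A constant table
#' (\eqn{\Delta_{max} = 0}) gives all grades 1 by convention.
#'
#' @param responses A [response_table].
#' @param tree An [indicator_tree] supplying global leaf weights.
#' @param rho Distinguishing coefficient in (0, 1], default 0.5.
#' @param reference Reference rating applied to every leaf (default: the top
#'   of the 1-5 axis).
#' @return Named numeric vector of relational grades, one per respondent.
#' @export
grey_relational_score <- function(responses, tree, rho = 0.5, reference = 5) {
  stopifnot(inherits(responses, "response_table"),
            inherits(tree, "indicator_tree"))
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  leaves <- leaf_ids(tree)
  x <- as.matrix(as.data.frame(responses)[, leaves, drop = FALSE])
  storage.mode(x) <- "double"
  delta <- abs(reference - x)
  dmin <- min(delta, na.rm = TRUE)
  dmax <- max(delta, na.rm = TRUE)
  ids <- responses$respondent_id
  if (dmax == 0)
    return(stats::setNames(rep(1, nrow(x)), ids))
  gamma <- (dmin + rho * dmax) / (delta + rho * dmax)
  w <- global_leaf_weights(tree)[leaves]
  w <- w / sum(w)
  stats::setNames(as.vector(gamma %*% w), ids)
}
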