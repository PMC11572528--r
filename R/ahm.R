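#' Saaty pairwise comparison matrices
#'
#' A positive reciprocal matrix of relative-importance judgments on the Saaty
#' 1-9 scale: `b[i, j] = k` means item i is k times as important as item j,
#' with `b[j, i] = 1/k` and unit diagonal. Entries off the Saaty lattice
#' (e.g. 2.5) are accepted with a warning, since geometric-mean aggregation
#' across experts produces them.
#'
#' @param b Square numeric matrix.
#' @param item_ids Optional labels (default: dimnames or `item1..n`).
#' @param tol Reciprocity tolerance: `|b[i,j] * b[j,i] - 1| <= tol`.
#' @return Object of class `comparison_matrix`.
#' @export
comparison_matrix <- function(b, item_ids = NULL, tol = 1e-9) {
  b <- as.matrix(b)
  n <- nrow(b)
  if (n != ncol(b)) stop("comparison matrix must be square")
  if (any(!is.finite(b)) || any(b <= 0))
    stop("comparison matrix entries must be positive and finite")
  if (any(abs(diag(b) - 1) > tol)) stop("comparison matrix diagonal must be 1")
  if (any(abs(b * t(b) - 1) > tol))
    stop("comparison matrix is not reciprocal (b[j,i] != 1/b[i,j])")
  if (is.null(item_ids))
    item_ids <- if (!is.null(rownames(b))) rownames(b) else paste0("item", seq_len(n))
  if (length(item_ids) != n) stop("item_ids length does not match matrix order")
  off <- b[upper.tri(b)]
  if (any(abs(off - round(off)) > 1e-8 & abs(1 / off - round(1 / off)) > 1e-8))
    warning("entries off the Saaty 1-9 lattice present (expected after aggregation)")
  dimnames(b) <- list(item_ids, item_ids)
  structure(list(item_ids = as.character(item_ids), b = b),
            class = "comparison_matrix")
}

#' Convert a comparison matrix to an AHM attribute-measure matrix
#'
#' The Attribute Hierarchy Model replaces the eigenvector computation of AHP
#' by a conversion of each pairwise judgment into a pair of relative-attribute
#' measures summing to 1: for `b[i,j] = k > 1`,
#' \deqn{u_{ij} = \frac{\beta k}{\beta k + 1},\qquad u_{ji} = \frac{1}{\beta k + 1},}
#' for `k = 1` (i != j) both measures are 0.5, and the diagonal is 0. The same
#' formula covers non-integer k > 1 arising from expert aggregation.
#'
#' @param m A [comparison_matrix].
#' @param beta Conversion parameter beta > 0 (default 2, the customary choice).
#' @return Object of class `attribute_measure` with fields `u` and `beta`.
#' @examples
#' m <- comparison_matrix(rbind(c(1, 3), c(1/3, 1)))
#' to_attribute_measure(m, beta = 2)$u  # u12 = 6/7, u21 = 1/7
#' @export
to_attribute_measure <- function(m, beta = 2) {
  stopifnot(inherits(m, "comparison_matrix"))
  if (!(beta > 0)) stop("beta must be > 0")
  b <- m$b
  n <- nrow(b)
  u <- matrix(0, n, n, dimnames = dimnames(b))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- b[i, j]
    u[i, j] <- if (abs(k - 1) <= 1e-9) 0.5
               else if (k > 1) beta * k / (beta * k + 1)
               else 1 / (beta / k + 1)   # b[j,i] = 1/k > 1
  }
  structure(list(u = u, beta = beta, item_ids = m$item_ids),
            class = "attribute_measure")
}

#' AHM weights from an attribute-measure matrix
#'
#' Scaled row sums: \eqn{w_i = \frac{2}{n(n-1)} \sum_j u_{ij}}. Because the
#' off-diagonal pairs of `u` sum to 1, the weights sum to 1 exactly (up to
#' floating round-off) and are non-negative for any valid input — no
#' consistency requirement is involved.
#'
#' @param u An [to_attribute_measure] result, or a [comparison_matrix] (then
#'   converted first with `beta`).
#' @param beta Conversion parameter used when `u` is a comparison matrix.
#' @return Named weight vector summing to 1.
#' @export
ahm_weights <- function(u, beta = 2) {
  if (inherits(u, "comparison_matrix")) u <- to_attribute_measure(u, beta)
  stopifnot(inherits(u, "attribute_measure"))
  n <- nrow(u$u)
  if (n < 2L) stop("at least 2 items are needed to derive weights")
  stats::setNames(2 / (n * (n - 1)) * rowSums(u$u), u$item_ids)
}

# Saaty random consistency index, orders 1..15
.SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
               1.51, 1.54, 1.56, 1.57, 1.59)

#' Classical AHP eigenvector weights and consistency ratio
#'
#' Principal-eigenvector weights by power iteration on the positive reciprocal
#' matrix, with the consistency index `CI = (lambda_max - n) / (n - 1)` and
#' consistency ratio `CR = CI / RI(n)` against the standard Saaty random
#' index table (orders up to 15). Provided as a diagnostic cross-check of the
#' AHM weights; AHM itself imposes no consistency requirement.
#'
#' @param m A [comparison_matrix] with at most 15 items.
#' @param max_iter Power-iteration cap.
#' @param tol Convergence tolerance on the weight vector.
#' @return List with `weights` (sum 1), `lambda_max`, `CI` and `CR`
#'   (`CR = 0` for n <= 2).
#' @export
ahp_eigen_weights <- function(m, max_iter = 1000L, tol = 1e-12) {
  stopifnot(inherits(m, "comparison_matrix"))
  b <- m$b
  n <- nrow(b)
  if (n > 15L) stop("Saaty RI table covers orders up to 15")
  w <- rep(1 / n, n)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    v <- as.vector(b %*% w)
    w_new <- v / sum(v)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
                 max_iter, delta))
  lambda <- mean(as.vector(b %*% w) / w)
  CI <- if (n > 1) (lambda - n) / (n - 1) else 0
  CR <- if (n <= 2) 0 else CI / .SAATY_RI[n]
  list(weights = stats::setNames(w, m$item_ids), lambda_max = lambda,
       CI = CI, CR = CR)
}

#' Pool expert comparison matrices
#'
#' Element-wise geometric mean over experts — the standard aggregation that
#' preserves reciprocity. Per-expert weight averaging is available via
#' `method = "weights"` (arithmetic mean of each expert's AHM weights,
#' renormalized), but the geometric mean of judgments is the default.
#'
#' @param matrices List of [comparison_matrix] objects sharing `item_ids`.
#' @param method `"geometric"` (pool judgments) or `"weights"` (pool AHM
#'   weight vectors; returns a weight vector, not a matrix).
#' @param beta Used only by `method = "weights"`.
#' @return A [comparison_matrix] (geometric) or a named weight vector.
#' @export
aggregate_experts <- function(matrices, method = c("geometric", "weights"),
                              beta = 2) {
  method <- match.arg(method)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "comparison_matrix")))
  ids <- matrices[[1L]]$item_ids
  for (m in matrices)
    if (!identical(m$item_ids, ids)) stop("matrices do not share item_ids")
  if (method == "weights") {
    w <- rowMeans(vapply(matrices, ahm_weights, numeric(length(ids)), beta = beta))
    return(w / sum(w))
  }
  logb <- Reduce(`+`, lapply(matrices, function(m) log(m$b))) / length(matrices)
  g <- exp(logb)
  g <- (g + 1 / t(g)) / 2          # kill round-off drift in reciprocity
  diag(g) <- 1
  suppressWarnings(comparison_matrix(g, item_ids = ids))
}

#' Re-weight an indicator tree from expert comparison matrices
#'
#' For every internal node (and the implicit root over the first-level
#' indicators, keyed `"(root)"`), the per-expert matrices over exactly its
#' children are pooled with [aggregate_experts] and converted to AHM weights;
#' single-child groups need no matrix and get weight 1.
#'
#' @param tree An [indicator_tree] giving the structure (weights are replaced).
#' @param matrices Named list: parent id -> list of [comparison_matrix]
#'   objects over that node's children.
#' @param beta AHM conversion parameter.
#' @return A new [indicator_tree] with AHM local weights (sibling sums exactly
#'   1 up to round-off).
#' @export
weight_tree <- function(tree, matrices, beta = 2) {
  stopifnot(inherits(tree, "indicator_tree"))
  nodes <- as.data.frame(tree)
  parents <- c("(root)", nodes$id[nodes$level < 3L])
  extra <- setdiff(names(matrices), parents)
  if (length(extra))
    stop("matrices supplied for unknown parent node(s): ",
         paste(extra, collapse = ", "))
  for (p in parents) {
    kids <- .children(tree, p)
    if (length(kids) == 1L) {
      nodes$weight[match(kids, nodes$id)] <- 1
      next
    }
    ml <- matrices[[p]]
    if (is.null(ml))
      stop("no comparison matrices for sibling group under '", p, "'")
    if (inherits(ml, "comparison_matrix")) ml <- list(ml)
    pooled <- aggregate_experts(ml, beta = beta)
    if (!setequal(pooled$item_ids, kids))
      stop("matrices under '", p, "' do not cover exactly its children")
    w <- ahm_weights(pooled, beta = beta)
    nodes$weight[match(names(w), nodes$id)] <- as.numeric(w)
  }
  indicator_tree(nodes, sibling_tol = 1e-9, leaf_tol = 1e-9)
}

#' Sibling weight groups of a tree
#'
#' Named list mapping each internal node (and `"(root)"`) to the named local
#' weights of its children — the ground-truth format [panel_spec] consumes.
#'
#' @param tree An [indicator_tree].
#' @return Named list of named numeric vectors.
#' @export
tree_sibling_groups <- function(tree) {
  stopifnot(inherits(tree, "indicator_tree"))
  parents <- c("(root)", tree$id[tree$level < 3L])
  out <- lapply(parents, function(p) {
    kids <- .children(tree, p)
    stats::setNames(tree$weight[match(kids, tree$id)], kids)
  })
  stats::setNames(out, parents)
}

#' Read comparison matrices from files
#'
#' A square CSV (header row and first column of item ids) holds one matrix; a
#' YAML file keyed by parent node id may hold several expert matrices per
#' sibling group (each matrix a list of rows).
#'
#' @param path CSV or YAML path.
#' @return A [comparison_matrix] (CSV) or a named list of lists of
#'   [comparison_matrix] objects (YAML).
#' @export
load_comparison_matrices <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    return(comparison_matrix(as.matrix(df), item_ids = colnames(df)))
  }
  if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    return(lapply(y, function(group) lapply(group, function(m) {
      ids <- m$item_ids
      comparison_matrix(do.call(rbind, m$rows), item_ids = ids)
    })))
  }
  stop("unrecognised matrix format '.", ext, "'")
}
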