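#' Weighted three-level indicator trees
#'
#' An `indicator_tree` holds a three-level evaluation hierarchy: first-level
#' domains, second-level contents and third-level items (the questionnaire
#' leaves), each carrying a *local* weight within its sibling group. Local
#' weights of every sibling group sum to 1 (within a printing tolerance, since
#' published tables round to 3 decimals), and the product of the weights along
#' a leaf's root path gives its *global* weight.
#'
#' @param nodes A data frame with columns `id`, `parent_id` (`NA` for
#'   first-level nodes), `level` (1, 2 or 3), `weight` (local weight in
#'   \[0, 1\]) and optionally `text`.
#' @param sibling_tol Allowed deviation of each sibling group's weight sum
#'   from 1. Default `5e-3`, matching weights printed to 3 decimals.
#' @param leaf_tol Allowed deviation of the global leaf-weight sum from 1.
#' @return An object of class `indicator_tree`: the node data frame (ids
#'   lower-cased) with validated structure.
#' @examples
#' tree <- indicator_tree(data.frame(
#'   id = c("a", "a1", "a11"), parent_id = c(NA, "a", "a1"),
#'   level = 1:3, weight = c(1, 1, 1)))
#' global_leaf_weights(tree)
#' @export
indicator_tree <- function(nodes, sibling_tol = 5e-3, leaf_tol = 1e-2) {
  stopifnot(is.data.frame(nodes))
  req <- c("id", "parent_id", "level", "weight")
  miss <- setdiff(req, names(nodes))
  if (length(miss))
    stop("scale definition lacks column(s): ", paste(miss, collapse = ", "))
  if (!("text" %in% names(nodes))) nodes$text <- ""
  nodes$text[is.na(nodes$text)] <- ""
  nodes <- data.frame(
    id        = tolower(trimws(as.character(nodes$id))),
    parent_id = tolower(trimws(as.character(nodes$parent_id))),
    level     = as.integer(nodes$level),
    weight    = as.numeric(nodes$weight),
    text      = as.character(nodes$text),
    stringsAsFactors = FALSE
  )
  nodes$parent_id[nodes$parent_id %in% c("", "na")] <- NA_character_
  validate_indicator_tree(nodes, sibling_tol = sibling_tol, leaf_tol = leaf_tol)
  structure(nodes, class = c("indicator_tree", "data.frame"))
}

validate_indicator_tree <- function(nodes, sibling_tol = 5e-3, leaf_tol = 1e-2) {
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stop("duplicate indicator id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(nodes$level %in% 1:3))
    stop("levels must be 1, 2 or 3; offending id(s): ",
         paste(nodes$id[!nodes$level %in% 1:3], collapse = ", "))
  bad_w <- nodes$id[is.na(nodes$weight) | nodes$weight < 0 | nodes$weight > 1]
  if (length(bad_w))
    stop("weight outside [0, 1] for id(s): ", paste(bad_w, collapse = ", "))
  # parent structure: level k > 1 must point at an existing level k-1 node
  top <- nodes$level == 1L
  if (any(!is.na(nodes$parent_id[top])))
    stop("first-level node(s) must have no parent: ",
         paste(nodes$id[top & !is.na(nodes$parent_id)], collapse = ", "))
  if (!any(top)) stop("tree has no first-level node")
  for (lv in 2:3) {
    at <- nodes$level == lv
    if (lv == 3L && !any(at)) stop("tree has no third-level (leaf) node")
    orphan <- at & (is.na(nodes$parent_id) | !(nodes$parent_id %in% nodes$id))
    if (any(orphan))
      stop("missing parent for id(s): ", paste(nodes$id[orphan], collapse = ", "))
    p_lv <- nodes$level[match(nodes$parent_id[at], nodes$id)]
    bad <- nodes$id[at][p_lv != lv - 1L]
    if (length(bad))
      stop("parent is not one level up for id(s): ", paste(bad, collapse = ", "))
  }
  # every level-1 / level-2 node must be internal (3-level connected tree)
  internal <- nodes$id[nodes$level < 3L]
  childless <- setdiff(internal, nodes$parent_id)
  if (length(childless))
    stop("internal node(s) without children: ", paste(childless, collapse = ", "))
  # sibling sums: each internal node's children, plus the first-level group
  groups <- c(list(`(root)` = which(top)),
              lapply(stats::setNames(internal, internal),
                     function(p) which(!is.na(nodes$parent_id) & nodes$parent_id == p)))
  for (g in names(groups)) {
    s <- sum(nodes$weight[groups[[g]]])
    if (abs(s - 1) > sibling_tol)
      stop(sprintf("sibling weights under '%s' sum to %.4f (tolerance %.0e)",
                   g, s, sibling_tol))
  }
  gw <- .leaf_weights(nodes)
  if (abs(sum(gw) - 1) > leaf_tol)
    stop(sprintf("global leaf weights sum to %.4f (tolerance %.0e)", sum(gw), leaf_tol))
  invisible(TRUE)
}

.leaf_weights <- function(nodes) {
  leaves <- nodes[nodes$level == 3L, ]
  w2 <- nodes$weight[match(leaves$parent_id, nodes$id)]
  p2 <- nodes$parent_id[match(leaves$parent_id, nodes$id)]
  w1 <- nodes$weight[match(p2, nodes$id)]
  stats::setNames(leaves$weight * w2 * w1, leaves$id)
}

#' Global leaf weights of an indicator tree
#'
#' The global weight of a leaf is the product of the local weights along its
#' root path; over the whole tree they sum to 1 (up to printing round-off).
#'
#' @param tree An [indicator_tree].
#' @return Named numeric vector, one entry per third-level indicator.
#' @export
global_leaf_weights <- function(tree) {
  stopifnot(inherits(tree, "indicator_tree"))
  .leaf_weights(tree)
}

#' Leaf ids of an indicator tree
#' @param tree An [indicator_tree].
#' @return Character vector of third-level indicator ids, in tree order.
#' @export
leaf_ids <- function(tree) tree$id[tree$level == 3L]

# children ids of a node ('(root)' for the first level), in tree order
.children <- function(tree, id) {
  if (identical(id, "(root)")) tree$id[tree$level == 1L]
  else tree$id[!is.na(tree$parent_id) & tree$parent_id == id]
}

#' Read a scale definition file
#'
#' Two dialects are accepted: a flat CSV (`id, parent_id, level, weight,
#' text`) and a hierarchical YAML in which each node is a mapping with keys
#' `id`, `text`, `weight` and (for internal nodes) `children`. Ids are
#' case-insensitive and stored lower-case.
#'
#' @param path Path to a `.csv`, `.yaml` or `.yml` file.
#' @inheritParams indicator_tree
#' @return A validated [indicator_tree]. Validation failures are reported with
#'   the offending node or sibling-group id.
#' @export
load_scale <- function(path, sibling_tol = 5e-3, leaf_tol = 1e-2) {
  if (!file.exists(path)) stop("scale file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  nodes <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character", parent_id = "character")),
    yaml = ,
    yml = .yaml_to_nodes(yaml::read_yaml(path)),
    stop("unrecognised scale format '.", ext, "' (expected .csv, .yaml or .yml)")
  )
  indicator_tree(nodes, sibling_tol = sibling_tol, leaf_tol = leaf_tol)
}

.yaml_to_nodes <- function(y) {
  rows <- list()
  walk <- function(node, parent, level) {
    if (is.null(node$id)) stop("YAML node without an 'id' (under parent '",
                               if (is.na(parent)) "(root)" else parent, "')")
    rows[[length(rows) + 1L]] <<- data.frame(
      id = node$id, parent_id = parent, level = level,
      weight = as.numeric(node$weight),
      text = if (is.null(node$text)) "" else node$text,
      stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, node$id, level + 1L)
  }
  for (n in y) walk(n, NA_character_, 1L)
  do.call(rbind, rows)
}

#' Write a scale definition file
#'
#' Inverse of [load_scale]; the written file re-loads to an identical tree.
#'
#' @param tree An [indicator_tree].
#' @param path Destination `.csv`, `.yaml` or `.yml` path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(tree, path) {
  stopifnot(inherits(tree, "indicator_tree"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(tree), path, row.names = FALSE, na = "")
  } else if (ext %in% c("yaml", "yml")) {
    as_list <- function(id) {
      i <- match(id, tree$id)
      node <- list(id = tree$id[i], text = tree$text[i], weight = tree$weight[i])
      kids <- .children(tree, id)
      if (length(kids)) node$children <- lapply(kids, as_list)
      node
    }
    yaml::write_yaml(lapply(.children(tree, "(root)"), as_list), path)
  } else stop("unrecognised scale format '.", ext, "'")
  invisible(path)
}

#' The packaged grassroots-medical-worker resilience scale
#'
#' Loads the published three-level emergency-resilience evaluation scale for
#' grassroots medical workers: 3 first-level indicators (professional quality
#' 0.346, psychological capital 0.614, emergency attitude 0.040), 13
#' second-level and 46 third-level indicators, with AHM-derived weights.
#'
#' @param format `"csv"` or `"yaml"`; both packaged transcriptions load to the
#'   same tree.
#' @return An [indicator_tree] with 62 nodes.
#' @examples
#' tree <- resilience_scale()
#' table(tree$level)
#' @export
resilience_scale <- function(format = c("csv", "yaml")) {
  format <- match.arg(format)
  f <- system.file("extdata", paste0("resilience_scale.", format),
                   package = "resilgrey", mustWork = TRUE)
  load_scale(f)
}

#' @export
print.indicator_tree <- function(x, ...) {
  cat(sprintf("Indicator tree: %d first-level, %d second-level, %d third-level\n",
              sum(x$level == 1), sum(x$level == 2), sum(x$level == 3)))
  for (top in x$id[x$level == 1L]) {
    i <- match(top, x$id)
    cat(sprintf("  %s (%.3f) %s\n", x$id[i], x$weight[i], x$text[i]))
    for (mid in .children(x, top)) {
      j <- match(mid, x$id)
      cat(sprintf("    %s (%.3f) %s [%d items]\n", x$id[j], x$weight[j],
                  x$text[j], length(.children(x, mid))))
    }
  }
  invisible(x)
}
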