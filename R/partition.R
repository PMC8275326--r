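# Hierarchical partition tree over the unit hypercube.  Nodes are
# environments (mutable, shared by reference across the optimizer state);
# each node is an axis-aligned box with a cached value at its center, either
# a ground-truth observation ("gt") or an upper confidence bound ("ucb").

new_interval <- function(lower, upper, depth, parent_id, counter) {
  node <- new.env(parent = emptyenv())
  node$lower <- lower
  node$upper <- upper
  node$center <- (lower + upper) / 2
  node$depth <- depth
  node$value <- NA_real_
  node$value_kind <- "ucb"
  node$children <- list()
  node$divided <- FALSE
  node$config_index <- NA_integer_  # finite-candidate row assigned, if any
  node$x_obs <- NULL                # scaled coords of the actual observation
  node$exhausted <- FALSE           # no unused candidate could be assigned
  node$id <- counter$next_id
  counter$next_id <- counter$next_id + 1L
  class(node) <- "fbo_interval"
  node
}

#' Create a partition tree over the unit hypercube
#'
#' @param d Dimension (number of scaled parameters), a positive integer.
#' @return An object of class `fbo_tree` whose root box is `[0,1]^d`.
#' @export
fbo_tree <- function(d) {
  stopifnot(d >= 1)
  tree <- new.env(parent = emptyenv())
  tree$d <- as.integer(d)
  tree$counter <- new.env(parent = emptyenv())
  tree$counter$next_id <- 1L
  tree$root <- new_interval(rep(0, d), rep(1, d), 0L, NA_integer_, tree$counter)
  class(tree) <- "fbo_tree"
  tree
}

#' @export
print.fbo_tree <- function(x, ...) {
  df <- tree_df(x)
  cat(sprintf("<fbo_tree> d=%d nodes=%d leaves=%d max_depth=%d evaluated=%d\n",
              x$d, nrow(df), sum(df$leaf), max(df$depth),
              sum(df$value_kind == "gt" & df$leaf)))
  invisible(x)
}

#' Trisect an interval along its longest dimension
#'
#' Splits the box into three equal parts along the side of maximal length
#' (ties broken toward the lowest-index dimension).  The middle child has the
#' same center as the parent and inherits the parent's value and value kind;
#' the outer children start as unevaluated ("ucb") placeholders whose values
#' the surrogate fills in.
#'
#' @param tree The `fbo_tree` owning the node.
#' @param node An undivided `fbo_interval` of the tree.
#' @return Invisibly, the list of the three children (left, middle, right).
#' @export
trisect <- function(tree, node) {
  if (node$divided) stop("interval is already divided")
  side <- node$upper - node$lower
  j <- which.max(side)  # ties -> lowest index
  w <- side[j] / 3
  mk <- function(k) {
    lo <- node$lower
    hi <- node$upper
    lo[j] <- node$lower[j] + (k - 1) * w
    hi[j] <- node$lower[j] + k * w
    new_interval(lo, hi, node$depth + 1L, node$id, tree$counter)
  }
  children <- list(mk(1), mk(2), mk(3))
  mid <- children[[2]]
  mid$value <- node$value
  mid$value_kind <- node$value_kind
  mid$config_index <- node$config_index
  mid$x_obs <- node$x_obs
  node$children <- children
  node$divided <- TRUE
  invisible(children)
}

# depth-first collection of every node in the tree
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

# order node list by (depth ascending, center lexicographic): the canonical
# deterministic ordering exposed to downstream modules
order_nodes <- function(nodes) {
  if (length(nodes) == 0L) return(nodes)
  depth <- vapply(nodes, function(n) n$depth, integer(1))
  centers <- do.call(rbind, lapply(nodes, function(n) n$center))
  keys <- c(list(depth), lapply(seq_len(ncol(centers)), function(j) centers[, j]))
  nodes[do.call(order, keys)]
}

#' Leaves of the partition tree
#'
#' @param tree An `fbo_tree`.
#' @return Undivided nodes, ordered by depth then lexicographic center.
#' @export
tree_leaves <- function(tree) {
  nodes <- tree_nodes(tree)
  order_nodes(Filter(function(n) !n$divided, nodes))
}

#' Unevaluated leaves
#'
#' Leaves whose cached value is a UCB rather than a ground-truth observation,
#' in deterministic (depth, lexicographic-center) order.  Leaves for which the
#' finite candidate set has been exhausted are excluded when
#' `include_exhausted = FALSE` (the default): they can never be evaluated.
#'
#' @param tree An `fbo_tree`.
#' @param include_exhausted Keep leaves with no assignable candidate left.
#' @return List of `fbo_interval` nodes.
#' @export
unevaluated_leaves <- function(tree, include_exhausted = FALSE) {
  Filter(function(n) n$value_kind == "ucb" &&
           (include_exhausted || !n$exhausted),
         tree_leaves(tree))
}

#' Flatten a tree to a data frame
#'
#' One row per node: id, depth, box bounds, center, value, value kind,
#' leaf flag.  Useful for diagnostics and snapshots.
#'
#' @param tree An `fbo_tree`.
#' @return A data frame.
#' @export
tree_df <- function(tree) {
  nodes <- tree_nodes(tree)
  d <- tree$d
  centers <- do.call(rbind, lapply(nodes, function(n) n$center))
  colnames(centers) <- paste0("c", seq_len(d))
  df <- data.frame(
    id = vapply(nodes, function(n) n$id, integer(1)),
    depth = vapply(nodes, function(n) n$depth, integer(1)),
    value = vapply(nodes, function(n) n$value, numeric(1)),
    value_kind = vapply(nodes, function(n) n$value_kind, character(1)),
    leaf = !vapply(nodes, function(n) n$divided, logical(1))
  )
  cbind(df, as.data.frame(centers))
}

node_to_list <- function(node) {
  out <- list(
    id = node$id,
    lower = node$lower,
    upper = node$upper,
    depth = node$depth,
    value = node$value,
    value_kind = node$value_kind,
    divided = node$divided,
    exhausted = node$exhausted,
    config_index = node$config_index
  )
  if (!is.null(node$x_obs)) out$x_obs <- node$x_obs
  if (node$divided) out$children <- lapply(node$children, node_to_list)
  out
}

list_to_node <- function(lst, tree) {
  node <- new_interval(as.numeric(lst$lower), as.numeric(lst$upper),
                       as.integer(lst$depth), NA_integer_, tree$counter)
  node$id <- as.integer(lst$id)
  node$value <- if (is.null(lst$value)) NA_real_ else as.numeric(lst$value)
  node$value_kind <- lst$value_kind
  node$exhausted <- isTRUE(lst$exhausted)
  node$config_index <- if (is.null(lst$config_index) || length(lst$config_index) == 0)
    NA_integer_ else as.integer(lst$config_index)
  if (!is.null(lst$x_obs)) node$x_obs <- as.numeric(lst$x_obs)
  if (isTRUE(lst$divided)) {
    node$divided <- TRUE
    node$children <- lapply(lst$children, list_to_node, tree = tree)
  }
  node
}

#' Serialize a partition tree to JSON
#'
#' Human-readable nested representation; `tree_from_json()` restores it
#' losslessly (box geometry, depths, values, kinds, division structure).
#'
#' @param tree An `fbo_tree`.
#' @return A JSON string.
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(list(d = tree$d, root = node_to_list(tree$root)),
                   auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null")
}

#' Restore a partition tree from JSON
#'
#' @param json A string produced by [tree_to_json()].
#' @return An `fbo_tree`.
#' @export
tree_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  tree <- fbo_tree(lst$d)
  tree$root <- list_to_node(lst$root, tree)
  ids <- vapply(tree_nodes(tree), function(n) n$id, integer(1))
  tree$counter$next_id <- max(ids) + 1L
  tree
}
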