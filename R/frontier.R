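# The frontier: unevaluated leaves encoded as (tree depth, UCB) points; the
# batch-candidate set is the upper convex hull of that scatter.  Depth is
# inversely proportional to box size, so the hull spans the
# exploration/exploitation trade-off: shallow nodes are large unexplored
# volumes, deep nodes sit near the incumbent.

#' Compute the frontier of a set of candidate points
#'
#' Input is one row per unevaluated leaf with its tree depth and the UCB of
#' the objective at its center.  Points dominated at their own depth (another
#' point at the same depth with strictly greater UCB) are removed first; the
#' remaining points on the upper convex hull of the (depth, UCB) scatter are
#' returned.  Collinear hull points are included.  Ties at the same depth and
#' UCB are broken by lexicographic center so the result is deterministic.
#'
#' @param depth Integer vector of tree depths.
#' @param ucb Numeric vector of UCB values (same length).
#' @param centers Optional matrix of node centers (rows) used only for
#'   deterministic tie-breaking.
#' @return Integer indices of the frontier points into the input, ordered by
#'   UCB descending, then depth ascending, then lexicographic center.
#' @export
compute_frontier <- function(depth, ucb, centers = NULL) {
  n <- length(depth)
  stopifnot(length(ucb) == n)
  if (n == 0L) return(integer(0))
  if (is.null(centers)) centers <- matrix(0, nrow = n, ncol = 1)
  centers <- as.matrix(centers)

  # canonical order: depth asc, ucb desc, center lexicographic
  keys <- c(list(depth, -ucb),
            lapply(seq_len(ncol(centers)), function(j) centers[, j]))
  ord <- do.call(order, keys)

  # per-depth dominance: keep only the maximal-UCB point at each depth
  # (first in canonical order)
  keep <- ord[!duplicated(depth[ord])]

  if (length(keep) > 2L) {
    # upper hull, Andrew's monotone chain over x = depth, y = ucb;
    # x strictly increasing after dominance removal. A middle point is
    # popped only when strictly below the chord, so collinear points stay.
    x <- depth[keep]
    y <- ucb[keep]
    chain <- integer(0)
    for (i in seq_along(keep)) {
      while (length(chain) >= 2L) {
        a <- chain[length(chain) - 1L]
        b <- chain[length(chain)]
        cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
        if (cross > 0) chain <- chain[-length(chain)] else break
      }
      chain <- c(chain, i)
    }
    keep <- keep[chain]
  }

  # add back non-dominated ties: points at a kept depth whose UCB equals the
  # depth maximum coincide in (depth, UCB) and also lie on the hull
  tie <- which(depth %in% depth[keep] & !(seq_len(n) %in% keep))
  tie <- tie[vapply(tie, function(i) {
    ucb[i] == max(ucb[depth == depth[i]])
  }, logical(1))]
  keep <- c(keep, tie)

  # output order: ucb desc, depth asc, center lexicographic
  okeys <- c(list(-ucb[keep], depth[keep]),
             lapply(seq_len(ncol(centers)), function(j) centers[keep, j]))
  keep[do.call(order, okeys)]
}

#' Fill the experiment queue from the frontier
#'
#' Mandatory nodes (those a serial bound-based run would evaluate) come
#' first, in the order given; the remaining slots are filled with frontier
#' nodes not already present, in frontier order (highest UCB first).  All
#' mandatory nodes are always included even when they exceed `k` — the
#' serial-inclusion guarantee takes precedence over the cap, and the caller
#' dispatches oversized batches in FIFO chunks of `k`.  If the frontier is
#' smaller than the remaining space the under-full batch is returned as is.
#'
#' @param frontier_ids Vector of node ids on the frontier, ordered by UCB
#'   descending.
#' @param mandatory_ids Vector of node ids that must be evaluated, FIFO order.
#' @param k Positive integer parallelism level.
#' @return Vector of node ids, length `max(length(mandatory_ids), <= k)`.
#' @export
fill_queue <- function(frontier_ids, mandatory_ids, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("`k` must be a positive integer")
  batch <- mandatory_ids
  extra <- setdiff(frontier_ids, mandatory_ids)
  room <- max(0L, k - length(batch))
  c(batch, utils::head(extra, room))
}
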