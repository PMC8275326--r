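# The main closed-loop optimizer.  One iteration is a full pass of three
# steps over the partition tree:
#   Step 1  walk the depths top-down and pick at most one division candidate
#           per depth, tracking the running best observed value; depths whose
#           best leaf is still unevaluated trigger a frontier computation and
#           a batch request before the depth is re-examined.
#   Step 2  look-ahead pruning: a candidate survives only if a virtual
#           trisection tree grown from it contains a UCB exceeding the value
#           of at least one deeper node of the real tree.
#   Step 3  surviving candidates are trisected; outer children whose UCB
#           beats the incumbent are mandatory evaluations, and the batch is
#           topped up to k from the frontier.
# The surrogate is refit once per iteration, after all ingests, and cached
# leaf UCBs are refreshed.  The loop stops at the evaluation budget.
# The algorithm is deterministic: no randomness outside the refit restarts,
# which use a fixed internal seed.

halt <- function(type) {
  cond <- structure(class = c(type, "fbo_halt", "condition"),
                    list(message = type, call = NULL))
  signalCondition(cond)
  stop(cond)
}

new_engine_state <- function(d, eval_fun, k, budget, lookahead, eta,
                             sigma, lengthscale, noise, kernel, refit,
                             refit_restarts, refit_seed, max_iterations,
                             lab, async) {
  st <- new.env(parent = emptyenv())
  st$d <- as.integer(d)
  st$tree <- fbo_tree(d)
  st$gp <- gp_new(sigma, lengthscale, noise, kernel)
  st$policy <- ucb_policy(eta)
  st$eval_fun <- eval_fun
  st$k <- as.integer(k)
  st$budget <- as.integer(budget)
  st$lookahead <- as.integer(lookahead)
  st$refit <- refit
  st$refit_restarts <- refit_restarts
  st$refit_seed <- refit_seed
  st$max_iterations <- max_iterations
  st$lab <- lab
  st$async <- async
  st$nu_max <- -Inf
  st$incumbent_x <- NULL
  st$incumbent_config <- NULL
  st$N <- 0L
  st$iteration <- 0L
  st$batch_counter <- 0L
  st$history <- list()
  st$frontier_log <- list()
  st$serial_log <- list()
  st$suggestions <- list()
  st$divisions_this_iter <- 0L
  st$evals_this_iter <- 0L
  class(st) <- "fbo_state"
  st
}

ingest_result <- function(state, node, res, batch_index) {
  node$value <- res$value
  node$value_kind <- "gt"
  node$x_obs <- res$x_obs
  if (!is.null(res$index)) node$config_index <- res$index
  state$gp <- gp_add(state$gp, res$x_obs, res$value)
  state$N <- state$N + 1L
  state$evals_this_iter <- state$evals_this_iter + 1L
  if (res$value > state$nu_max) {
    state$nu_max <- res$value
    state$incumbent_x <- res$x_obs
    state$incumbent_config <- res$config
  }
  row <- list(eval = state$N, iteration = state$iteration,
              batch = batch_index, value = res$value,
              best_so_far = state$nu_max, depth = node$depth,
              node_id = node$id)
  for (j in seq_along(res$x_obs)) row[[paste0("x", j)]] <- res$x_obs[[j]]
  row$config_index <- if (is.null(res$index)) NA_integer_ else res$index
  if (!is.null(res$time_done)) row$time_done <- res$time_done
  state$history[[length(state$history) + 1L]] <- row
  if (isTRUE(state$async) && state$refit) state$gp <- engine_refit(state)
  invisible(state)
}

engine_refit <- function(state) {
  if (gp_n(state$gp) < 2L) return(state$gp)
  gp_refit(state$gp, restarts = state$refit_restarts,
           seed = state$refit_seed)
}

# recompute cached UCB values of all unevaluated leaves under the current
# surrogate (the model changes every refit, so cached bounds go stale)
refresh_leaf_ucbs <- function(state) {
  leaves <- unevaluated_leaves(state$tree, include_exhausted = TRUE)
  if (length(leaves) == 0L) return(invisible(state))
  centers <- do.call(rbind, lapply(leaves, function(n) n$center))
  u <- gp_ucb(state$gp, state$policy, centers)
  for (i in seq_along(leaves)) leaves[[i]]$value <- u[[i]]
  invisible(state)
}

# frontier over the potentially optimal unevaluated leaves (UCB at least
# the incumbent: a leaf the model believes cannot beat the best observed
# value is never requested); returns nodes in frontier order (UCB
# descending) with freshly computed UCB coordinates
frontier_nodes <- function(state) {
  leaves <- unevaluated_leaves(state$tree)
  if (length(leaves) == 0L) return(list())
  centers <- do.call(rbind, lapply(leaves, function(n) n$center))
  u <- gp_ucb(state$gp, state$policy, centers)
  for (i in seq_along(leaves)) leaves[[i]]$value <- u[[i]]
  ok <- u >= state$nu_max
  if (!any(ok)) return(list())
  leaves <- leaves[ok]
  centers <- centers[ok, , drop = FALSE]
  u <- u[ok]
  depths <- vapply(leaves, function(n) n$depth, integer(1))
  idx <- compute_frontier(depths, u, centers)
  snap <- data.frame(iteration = state$iteration, depth = depths, ucb = u,
                     selected = seq_along(leaves) %in% idx)
  snap <- cbind(snap, as.data.frame(centers))
  state$frontier_log[[length(state$frontier_log) + 1L]] <- snap
  leaves[idx]
}

# dispatch nodes for evaluation in FIFO chunks of at most k, honoring the
# remaining budget; results are ingested in batch order (barrier mode) or in
# virtual completion order with a refit per arrival (async mode)
dispatch_nodes <- function(state, nodes) {
  nodes <- Filter(function(n) n$value_kind == "ucb" && !n$exhausted, nodes)
  # drop duplicates by id, preserving order
  if (length(nodes) > 1L) {
    ids <- vapply(nodes, function(n) n$id, integer(1))
    nodes <- nodes[!duplicated(ids)]
  }
  while (length(nodes) > 0L) {
    remaining <- state$budget - state$N
    if (remaining <= 0L) halt("fbo_budget")
    chunk <- utils::head(nodes, min(state$k, remaining))
    nodes <- nodes[-seq_along(chunk)]
    state$batch_counter <- state$batch_counter + 1L
    results <- vector("list", length(chunk))
    for (i in seq_along(chunk)) {
      results[[i]] <- state$eval_fun(chunk[[i]])
    }
    status <- vapply(results, function(r) r$status, character(1))
    for (i in which(status == "exhausted")) chunk[[i]]$exhausted <- TRUE
    for (i in which(status == "unknown")) {
      state$suggestions[[length(state$suggestions) + 1L]] <-
        list(node = chunk[[i]], config = results[[i]]$config,
             center = chunk[[i]]$center)
    }
    ok <- which(status == "ok")
    if (!is.null(state$lab) && length(ok) > 0L) {
      ack <- lab_submit(state$lab, n = length(ok))
      for (j in seq_along(ok)) results[[ok[j]]]$time_done <- ack$done[j]
      if (isTRUE(state$async)) ok <- ok[order(ack$done, seq_along(ok))]
    }
    for (i in ok) {
      if (state$N >= state$budget) halt("fbo_budget")
      ingest_result(state, chunk[[i]], results[[i]], state$batch_counter)
    }
    if (length(state$suggestions) > 0L) halt("fbo_await")
  }
  invisible(state)
}

# record, for every batch construction, the node a serial (k = 1) run of
# the same state would have requested alongside the actual batch — the
# serial-inclusion guarantee is then checkable on any run
log_serial_pick <- function(state, frontier_ids, mandatory_ids, batch_ids) {
  serial <- fill_queue(frontier_ids, mandatory_ids, 1L)
  if (length(serial) == 0L || length(batch_ids) == 0L) return(invisible())
  state$serial_log[[length(state$serial_log) + 1L]] <-
    list(iteration = state$iteration, serial = serial[1L],
         batch = batch_ids)
  invisible()
}

leaves_at_depth <- function(tree, p) {
  Filter(function(n) n$depth == p, tree_leaves(tree))
}

nodes_at_depth <- function(tree, p) {
  Filter(function(n) n$depth == p, tree_nodes(tree))
}

tree_max_depth <- function(tree) {
  max(vapply(tree_nodes(tree), function(n) n$depth, integer(1)))
}

# best leaf at a depth by cached value, ties by lexicographic center
best_leaf <- function(leaves) {
  vals <- vapply(leaves, function(n) n$value, numeric(1))
  vals[is.na(vals)] <- -Inf
  best <- max(vals)
  cands <- order_nodes(leaves[vals == best])
  cands[[1]]
}

# Step 1: identify at most one division candidate per depth, top-down,
# tracking the running best observed value; an unevaluated depth-best leaf
# triggers a frontier batch request and the depth is re-examined.  The
# running value starts at the root's ground truth (the default incumbent)
# and is updated only when a candidate is selected.
step1_identify <- function(state) {
  cands <- list()
  nu_run <- if (state$tree$root$value_kind == "gt" &&
                !is.na(state$tree$root$value))
    state$tree$root$value else -Inf
  p <- 0L
  while (p <= tree_max_depth(state$tree)) {
    repeat {
      leaves <- leaves_at_depth(state$tree, p)
      if (length(leaves) == 0L) break
      best <- best_leaf(leaves)
      if (best$value_kind == "gt") {
        if (!is.na(best$value) && best$value >= nu_run) {
          cands[[length(cands) + 1L]] <- best
          nu_run <- best$value
        }
        break
      }
      if (best$exhausted) break
      # case 3: unevaluated depth-best leaf; frontier fills the batch, the
      # depth-best leaf itself is the mandatory request
      fr <- frontier_nodes(state)
      fr_ids <- vapply(fr, function(n) n$id, integer(1))
      ids <- fill_queue(fr_ids, best$id, state$k)
      log_serial_pick(state, fr_ids, best$id, ids)
      pool <- c(list(best), fr)
      pool_ids <- vapply(pool, function(n) n$id, integer(1))
      dispatch_nodes(state, pool[match(ids, pool_ids)])
      if (best$value_kind == "ucb" && best$exhausted) break
      if (best$value_kind == "ucb" && !best$exhausted) break  # safety
    }
    p <- p + 1L
  }
  cands
}

# centers of every node of a virtual trisection tree grown from a box for
# `levels` rounds of division (pure geometry; nothing touches the real tree)
virtual_centers <- function(lower, upper, levels) {
  if (levels <= 0L) return(NULL)
  out <- list()
  grow <- function(lo, hi, lev) {
    side <- hi - lo
    j <- which.max(side)
    w <- side[j] / 3
    for (kk in 1:3) {
      l2 <- lo; h2 <- hi
      l2[j] <- lo[j] + (kk - 1) * w
      h2[j] <- lo[j] + kk * w
      out[[length(out) + 1L]] <<- (l2 + h2) / 2
      if (lev > 1L) grow(l2, h2, lev - 1L)
    }
  }
  grow(lower, upper, levels)
  do.call(rbind, out)
}

# Step 2: look-ahead pruning.  A candidate at depth p is kept iff the
# virtual tree grown from it contains a UCB greater than the value of at
# least one real node deeper than p (vacuously kept when no deeper nodes
# exist, or when look-ahead is disabled).
step2_prune <- function(state, cands) {
  if (state$lookahead <= 0L || length(cands) == 0L) return(cands)
  all_nodes <- tree_nodes(state$tree)
  depths <- vapply(all_nodes, function(n) n$depth, integer(1))
  vals <- vapply(all_nodes, function(n) n$value, numeric(1))
  Filter(function(cand) {
    deeper <- vals[depths > cand$depth & !is.na(vals)]
    if (length(deeper) == 0L) return(TRUE)
    vc <- virtual_centers(cand$lower, cand$upper, state$lookahead)
    ucbs <- gp_ucb(state$gp, state$policy, vc)
    max(ucbs) > min(deeper)
  }, cands)
}

# Step 3: trisect the surviving candidates; outer children whose UCB beats
# the incumbent are mandatory evaluations, the rest keep their UCB as the
# cached node value; the batch is filled to k from the frontier.
step3_divide_and_select <- function(state, cands) {
  mandatory <- list()
  for (cand in cands) {
    if (cand$divided) next
    children <- trisect(state$tree, cand)
    state$divisions_this_iter <- state$divisions_this_iter + 1L
    for (child in children[c(1L, 3L)]) {
      u <- gp_ucb(state$gp, state$policy, child$center)
      child$value <- u
      if (u >= state$nu_max) mandatory[[length(mandatory) + 1L]] <- child
    }
  }
  fr <- frontier_nodes(state)
  fr_ids <- vapply(fr, function(n) n$id, integer(1))
  m_ids <- vapply(mandatory, function(n) n$id, integer(1))
  ids <- fill_queue(fr_ids, m_ids, state$k)
  log_serial_pick(state, fr_ids, m_ids, ids)
  pool <- c(mandatory, fr)
  pool_ids <- vapply(pool, function(n) n$id, integer(1))
  dispatch_nodes(state, pool[match(ids, pool_ids)])
  invisible(state)
}

engine_run <- function(state) {
  finished <- tryCatch({
    if (state$N == 0L) {
      dispatch_nodes(state, list(state$tree$root))
      if (state$refit) state$gp <- engine_refit(state)
      refresh_leaf_ucbs(state)
    }
    while (state$N < state$budget) {
      state$iteration <- state$iteration + 1L
      if (state$iteration > state$max_iterations) {
        warning("stopping: max_iterations reached before the budget")
        break
      }
      state$divisions_this_iter <- 0L
      state$evals_this_iter <- 0L
      cands <- step1_identify(state)
      kept <- step2_prune(state, cands)
      step3_divide_and_select(state, kept)
      if (state$refit) state$gp <- engine_refit(state)
      refresh_leaf_ucbs(state)
      if (!is.null(state$candidates) && all(state$candidates$used)) {
        message("stopping: candidate set exhausted before the budget")
        break
      }
      if (state$divisions_this_iter == 0L && state$evals_this_iter == 0L) {
        message("stopping: no divisions or evaluations possible")
        break
      }
    }
    TRUE
  },
  fbo_budget = function(e) TRUE,
  fbo_await = function(e) FALSE)
  state$awaiting <- !finished
  invisible(state)
}

history_df <- function(state) {
  if (length(state$history) == 0L) {
    return(data.frame(eval = integer(0), iteration = integer(0),
                      batch = integer(0), value = numeric(0),
                      best_so_far = numeric(0)))
  }
  cols <- names(state$history[[1L]])
  out <- lapply(cols, function(cl)
    unlist(lapply(state$history, function(r) r[[cl]]), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out)
}

engine_result <- function(state) {
  res <- list(
    best_value = state$nu_max,
    best_x = state$incumbent_x,
    best_config = state$incumbent_config,
    evaluations = state$N,
    iterations = state$iteration,
    history = history_df(state),
    tree = state$tree,
    gp = state$gp,
    frontier_log = if (length(state$frontier_log))
      do.call(rbind, state$frontier_log) else NULL,
    serial_log = state$serial_log,
    state = state
  )
  class(res) <- "fbo_result"
  res
}

#' @export
print.fbo_result <- function(x, ...) {
  cat("<fbo_result>\n")
  cat(sprintf("  evaluations: %d (iterations: %d)\n",
              x$evaluations, x$iterations))
  cat(sprintf("  best value:  %.6g\n", x$best_value))
  if (!is.null(x$best_config)) {
    cat("  best configuration:\n")
    for (nm in names(x$best_config))
      cat(sprintf("    %s = %s\n", nm, format(x$best_config[[nm]])))
  } else if (!is.null(x$best_x)) {
    cat(sprintf("  best x (scaled): %s\n",
                paste(format(x$best_x, digits = 6), collapse = ", ")))
  }
  invisible(x)
}

#' Optimize a black-box function over a continuous space
#'
#' Runs the deterministic batch optimizer against a function defined on the
#' unit hypercube (or, when `space` is given, on a native parameter space
#' that is scaled internally).  Evaluation starts at the center of the space
#' and proceeds by trisection of the partition tree; batches of up to `k`
#' points per request are selected from the convex-hull frontier.
#'
#' @param f Objective to maximize.  Without `space`: `f(x)` with `x` a
#'   numeric vector in `[0,1]^d`.  With `space`: `f(config)` with `config` a
#'   named list of native parameter values.
#' @param d Dimension (required when `space` is `NULL`).
#' @param space Optional [config_space()].
#' @param k Parallelism level (maximum batch size). Default 4.
#' @param budget Total number of function evaluations. Default 25.
#' @param lookahead Virtual-tree depth for Step-2 pruning. Default 4.
#' @param eta UCB confidence parameter. Default 0.05.
#' @param sigma,lengthscale,noise,kernel Surrogate settings, see [gp_new()].
#' @param refit Refit hyperparameters after each iteration. Default TRUE.
#' @param refit_restarts,refit_seed Multi-restart settings for [gp_refit()].
#' @param max_iterations Safety cap on the number of iterations.
#' @param lab Optional [lab_queue()] supplying virtual job timings.
#' @param async Ingest results in virtual completion order with a refit per
#'   arrival (requires `lab`). Default FALSE (per-iteration barrier).
#' @return An `fbo_result`: best value/point, history with a monotone
#'   best-so-far trace, the partition tree, the surrogate, frontier log.
#' @examples
#' res <- fbo_optimize(sinusoid_1d, d = 1, k = 4, budget = 20)
#' res$best_value
#' @export
fbo_optimize <- function(f, d = NULL, space = NULL, k = 4, budget = 25,
                         lookahead = 4, eta = 0.05, sigma = 1,
                         lengthscale = 0.25, noise = 1e-6,
                         kernel = "matern52", refit = TRUE,
                         refit_restarts = 5L, refit_seed = 0L,
                         max_iterations = 1000L, lab = NULL, async = FALSE) {
  stopifnot(budget >= 1)
  if (is.null(space) && is.null(d))
    stop("either `d` or `space` must be supplied")
  if (!is.null(space)) d <- space$d
  eval_fun <- function(node) {
    x <- node$center
    val <- if (is.null(space)) f(x) else f(space_unscale(space, x))
    cfg <- if (is.null(space)) NULL else space_unscale(space, x)
    list(status = "ok", value = as.numeric(val), x_obs = x,
         config = cfg, index = NULL)
  }
  state <- new_engine_state(d, eval_fun, k, budget, lookahead, eta, sigma,
                            lengthscale, noise, kernel, refit,
                            refit_restarts, refit_seed, max_iterations,
                            lab, async)
  engine_run(state)
  engine_result(state)
}

#' Optimize over a finite candidate set (replayed-dataset mode)
#'
#' The search still runs over the unit hypercube, but instead of evaluating
#' an interval's center directly, the nearest unused candidate configuration
#' (Euclidean distance in scaled space) is assigned to the interval and its
#' tabulated endpoint is returned; each configuration is used at most once.
#'
#' @param data Data frame of candidate configurations: one column per space
#'   parameter plus endpoint columns.
#' @param space A [config_space()] matching the parameter columns.
#' @param objective Either an endpoint name passed to [endpoint_objective()]
#'   (`"height"`, `"width"`, `"snr"`, `"combo1"`, `"combo2"`) or a numeric
#'   vector of objective values, one per row of `data` (maximize).
#' @inheritParams fbo_optimize
#' @param snr_direction Passed to [endpoint_objective()].
#' @return An `fbo_result`; `best_config` holds the winning native
#'   configuration and `history$config_index` the replayed row numbers.
#' @export
fbo_optimize_discrete <- function(data, space, objective = "height", k = 4,
                                  budget = 25, lookahead = 4, eta = 0.05,
                                  sigma = 1, lengthscale = 0.25,
                                  noise = 1e-6, kernel = "matern52",
                                  refit = TRUE, refit_restarts = 5L,
                                  refit_seed = 0L, max_iterations = 1000L,
                                  lab = NULL, async = FALSE,
                                  snr_direction = "maximize") {
  stopifnot(budget >= 1)
  obj <- if (is.character(objective))
    endpoint_objective(data, objective, snr_direction) else as.numeric(objective)
  stopifnot(length(obj) == nrow(data))
  cands <- candidate_set(space, data)
  eval_fun <- function(node) {
    a <- assign_center(cands, node$center)
    if (is.null(a)) return(list(status = "exhausted"))
    list(status = "ok", value = obj[a$index], x_obs = a$scaled,
         config = as.list(a$config), index = a$index)
  }
  state <- new_engine_state(space$d, eval_fun, k, budget, lookahead, eta,
                            sigma, lengthscale, noise, kernel, refit,
                            refit_restarts, refit_seed, max_iterations,
                            lab, async)
  state$candidates <- cands
  state$objective_values <- obj
  engine_run(state)
  res <- engine_result(state)
  res$found_optimum <- any(res$history$config_index == which.max(obj))
  res
}
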