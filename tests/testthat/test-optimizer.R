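test_that("budget 1 evaluates exactly the center of the space", {
  res <- fbo_optimize(sinusoid_1d, d = 1, budget = 1)
  expect_equal(res$evaluations, 1L)
  expect_equal(res$history$x1, 0.5)
  expect_equal(res$best_value, sinusoid_1d(0.5))
})

test_that("fresh 1-D tree: step 1 triggers a depth-1 frontier request", {
  st <- make_engine(1, sinusoid_1d, k = 2, budget = 10)
  frontierBO:::dispatch_nodes(st, list(st$tree$root))
  trisect(st$tree, st$tree$root)
  frontierBO:::refresh_leaf_ucbs(st)
  expect_length(unevaluated_leaves(st$tree), 2)
  n_before <- st$N
  cands <- frontierBO:::step1_identify(st)
  # the two outer depth-1 children were evaluated via the frontier batch
  expect_gte(st$N, n_before + 2L)
  expect_length(unevaluated_leaves(st$tree), 0)
  # after results arrive the depth is re-examined and a candidate emerges
  expect_gte(length(cands), 1L)
})

test_that("a depth whose best leaf falls below the running best is skipped", {
  st <- make_engine(1, function(x) 1 - abs(x - 0.5), budget = 30)
  frontierBO:::dispatch_nodes(st, list(st$tree$root))  # f(0.5) = 1, maximal
  trisect(st$tree, st$tree$root)
  ch <- st$tree$root$children
  # force ground-truth values below the root's on the outer children
  for (i in c(1, 3)) {
    ch[[i]]$value <- 0.2
    ch[[i]]$value_kind <- "gt"
  }
  cands <- frontierBO:::step1_identify(st)
  depths <- vapply(cands, function(n) n$depth, integer(1))
  # depth 1's best leaf is the inherited middle (1.0 >= running best);
  # the outer 0.2 leaves never become candidates
  vals <- vapply(cands, function(n) n$value, numeric(1))
  expect_true(all(vals >= 1))
})

test_that("look-ahead pruning keeps and drops candidates as specified", {
  st <- make_engine(1, function(x) 0, budget = 50, lookahead = 3)
  # candidate at the maximum depth: kept vacuously
  st$tree$root$value <- 0.5
  st$tree$root$value_kind <- "gt"
  kept <- frontierBO:::step2_prune(st, list(st$tree$root))
  expect_length(kept, 1)

  # lookahead 0: no pruning at all
  st$lookahead <- 0L
  expect_length(frontierBO:::step2_prune(st, list(st$tree$root)), 1)
  st$lookahead <- 3L

  # suppressed region: condition the surrogate so the candidate's box has
  # posterior mean far below a deeper node's value -> dropped
  st2 <- make_engine(1, function(x) 0, budget = 50, lookahead = 3)
  xs <- seq(0, 1 / 3, length.out = 15)
  st2$gp <- gp_add(st2$gp, matrix(xs), rep(-5, 15))
  st2$gp$sigma <- 0.05  # tight model: UCB in [0, 1/3] stays near -5
  st2$gp <- frontierBO:::gp_refresh(st2$gp)
  tr <- st2$tree
  tr$root$value <- -5
  tr$root$value_kind <- "gt"
  ch <- trisect(tr, tr$root)
  cand <- ch[[1]]                  # box [0, 1/3]
  cand$value <- -5
  cand$value_kind <- "gt"
  deep <- trisect(tr, ch[[3]])     # create depth-2 nodes
  deep[[2]]$value <- 0.9           # a deeper node with a high value
  deep[[2]]$value_kind <- "gt"
  expect_length(frontierBO:::step2_prune(st2, list(cand)), 0)
})

test_that("step 3 assigns UCB values below the incumbent instead of evaluating", {
  calls <- new.env(); calls$n <- 0L
  f <- function(x) { calls$n <<- calls$n + 1L; 0.1 }
  st <- make_engine(1, function(x) 0.1, budget = 50)
  st$nu_max <- 100  # incumbent far above any UCB
  st$tree$root$value <- 0.1
  st$tree$root$value_kind <- "gt"
  frontierBO:::step3_divide_and_select(st, list(st$tree$root))
  expect_true(st$tree$root$divided)
  # both outer children kept their UCB (no evaluation happened)
  expect_identical(st$N, 0L)
  expect_length(unevaluated_leaves(st$tree), 2)
  for (n in unevaluated_leaves(st$tree)) expect_lt(n$value, 100)
})

test_that("runs are deterministic and the incumbent trace is monotone", {
  r1 <- fbo_optimize(sinusoid_1d, d = 1, k = 4, budget = 20)
  r2 <- fbo_optimize(sinusoid_1d, d = 1, k = 4, budget = 20)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best_so_far) >= 0))
  expect_equal(r1$best_value, max(r1$history$value))
  # each configuration evaluated at most once
  expect_false(any(duplicated(r1$history$x1)))
})

test_that("discrete mode respects one-use and finds planted optima", {
  sw <- generate_sweep(sizes = c(4, 3, 2), family = "unimodal", seed = 4)
  res <- fbo_optimize_discrete(sw$data, sw$space, "height", k = 4,
                               budget = 15)
  expect_false(any(duplicated(res$history$config_index)))
  expect_true(all(diff(res$history$best_so_far) >= 0))
  expect_identical(res$evaluations, 15L)
  r2 <- fbo_optimize_discrete(sw$data, sw$space, "height", k = 4,
                              budget = 15)
  expect_identical(res$history, r2$history)
})

test_that("candidate exhaustion stops the loop gracefully", {
  sp <- config_space(param_levels("a", 1:3))
  data <- data.frame(a = 1:3, height = c(1, 3, 2))
  expect_message(
    res <- fbo_optimize_discrete(data, sp, "height", k = 2, budget = 10),
    "exhausted|stopping")
  expect_identical(res$evaluations, 3L)
  expect_equal(res$best_value, 1)  # scaled heights: max = 1
  expect_equal(as.integer(res$best_config$a), 2L)
})

test_that("serial inclusion: the k = 1 request heads every batch", {
  # with identical ingested history the k = 1 run's single request is the
  # first element of the ordered queue, which the k = 4 batch contains by
  # construction; verify on the replayed fixture that the first evaluation
  # of every iteration agrees between a k = 1 and a k = 4 run early on
  sw <- generate_sweep(family = "unimodal", seed = 2)
  r1 <- fbo_optimize_discrete(sw$data, sw$space, "height", k = 1, budget = 3)
  r4 <- fbo_optimize_discrete(sw$data, sw$space, "height", k = 4, budget = 9)
  # identical histories up to the first divergence point: the serial run's
  # requests appear in order within the batched run's requests
  expect_identical(r1$history$config_index[1], r4$history$config_index[1])
  expect_true(all(r1$history$config_index %in% r4$history$config_index))
})

test_that("async mode ingests in virtual completion order", {
  sw <- generate_sweep(sizes = c(4, 3, 2), family = "unimodal", seed = 4)
  lab <- lab_queue(4, latency_lognormal(seed = 9))
  res <- fbo_optimize_discrete(sw$data, sw$space, "height", k = 4,
                               budget = 12, lab = lab, async = TRUE)
  expect_identical(res$evaluations, 12L)
  expect_true(all(diff(res$history$best_so_far) >= 0))
  # completion times non-decreasing within each batch
  for (b in unique(res$history$batch)) {
    expect_false(is.unsorted(res$history$time_done[res$history$batch == b]))
  }
})
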