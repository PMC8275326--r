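test_that("trisection splits into exact thirds along the longest dimension", {
  # 1-D root: children centered at 1/6, 1/2, 5/6
  tr <- fbo_tree(1)
  tr$root$value <- 0.5
  tr$root$value_kind <- "gt"
  ch <- trisect(tr, tr$root)
  expect_equal(vapply(ch, function(n) n$center, numeric(1)),
               c(1 / 6, 1 / 2, 5 / 6))
  expect_true(tr$root$divided)
  expect_equal(ch[[2]]$value, 0.5)
  expect_identical(ch[[2]]$value_kind, "gt")
  expect_identical(ch[[1]]$value_kind, "ucb")
  expect_identical(ch[[3]]$value_kind, "ucb")
  expect_error(trisect(tr, tr$root), "already divided")

  # 2-D box [0,1] x [0,1/3]: longest side is dimension 1
  tr2 <- fbo_tree(2)
  node <- frontierBO:::new_interval(c(0, 0), c(1, 1 / 3), 1L, NA_integer_,
                                    tr2$counter)
  ch2 <- trisect(tr2, node)
  centers <- t(vapply(ch2, function(n) n$center, numeric(2)))
  expect_equal(centers,
               rbind(c(1 / 6, 1 / 6), c(1 / 2, 1 / 6), c(5 / 6, 1 / 6)))
})

test_that("children partition the parent box and inherit depth + 1", {
  set.seed(42)
  for (rep in 1:20) {
    d <- sample(1:4, 1)
    tr <- fbo_tree(d)
    lo <- runif(d, 0, 0.4)
    hi <- lo + runif(d, 0.1, 0.6)
    node <- frontierBO:::new_interval(lo, hi, 3L, NA_integer_, tr$counter)
    ch <- trisect(tr, node)
    vol <- function(n) prod(n$upper - n$lower)
    expect_equal(sum(vapply(ch, vol, numeric(1))), vol(node))
    expect_equal(ch[[2]]$center, node$center)
    expect_true(all(vapply(ch, function(n) n$depth, integer(1)) == 4L))
    # split dimension attains the maximal side
    side <- hi - lo
    j <- which(abs((ch[[1]]$upper - ch[[1]]$lower) - side) > 1e-12)
    expect_equal(side[j], max(side))
  }
})

test_that("leaf boxes always partition the unit hypercube (volume 1)", {
  f <- function(x) sum(sin(5 * x))
  st <- make_engine(2, f, budget = 20)
  frontierBO:::engine_run(st)
  leaves <- tree_leaves(st$tree)
  vols <- vapply(leaves, function(n) prod(n$upper - n$lower), numeric(1))
  expect_equal(sum(vols), 1, tolerance = 1e-12)
  # depth/size duality: longest side <= (1/3)^floor(depth/d)
  for (n in leaves) {
    expect_lte(max(n$upper - n$lower), (1 / 3)^floor(n$depth / 2) + 1e-12)
  }
})

test_that("unevaluated_leaves returns UCB leaves in deterministic order", {
  tr <- fbo_tree(1)
  tr$root$value <- 0.3
  tr$root$value_kind <- "gt"
  expect_length(unevaluated_leaves(tr), 0)
  ch <- trisect(tr, tr$root)
  ul <- unevaluated_leaves(tr)
  expect_length(ul, 2)
  expect_equal(vapply(ul, function(n) n$center, numeric(1)), c(1 / 6, 5 / 6))
  # ordering: depth ascending, then lexicographic center
  trisect(tr, ch[[1]])
  ul2 <- unevaluated_leaves(tr)
  depths <- vapply(ul2, function(n) n$depth, integer(1))
  expect_true(!is.unsorted(depths))
})

test_that("tree JSON serialization round-trips losslessly", {
  f <- function(x) sinusoid_1d(x[1])
  st <- make_engine(1, f, budget = 12)
  frontierBO:::engine_run(st)
  json <- tree_to_json(st$tree)
  tr2 <- tree_from_json(json)
  df1 <- tree_df(st$tree)
  df2 <- tree_df(tr2)
  expect_equal(df1, df2)
  expect_identical(as.character(tree_to_json(tr2)), as.character(json))
})
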