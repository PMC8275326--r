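test_that("min-max scaling and its degenerate case", {
  expect_equal(minmax_scale(c(1, 2, 3)), c(0, 0.5, 1))
  expect_warning(s <- minmax_scale(rep(5, 4)), "degenerate")
  expect_equal(s, rep(0.5, 4))
  x <- rnorm(50)
  s <- minmax_scale(x)
  expect_equal(s[which.min(x)], 0)
  expect_equal(s[which.max(x)], 1)
})

test_that("combo objectives follow their defining formulas", {
  expect_equal(combo1(1, 1), 2)
  expect_equal(combo1(0, 0.5), 2)
  expect_equal(combo1(0.3, 0.25), 4.3)
  expect_message(v <- combo1(0.5, 0), "clamped")
  expect_equal(v, 0.5 + 1 / 1e-3)

  expect_equal(combo2(0, 2.5), 2.5)
  expect_equal(combo2(1, 2), 3)
  # additivity in the snr term
  expect_equal(combo2(0.2, 1.1) + combo2(0.3, 0), combo2(0.5, 1.1))
})

test_that("resolution matches closed-form substitution and its invariances", {
  expect_equal(resolution(c(1, 2), c(0.1, 0.1), c = 1.18), 5.9)
  # additivity over adjacent pairs: 3 equally spaced peaks = 2x the pair value
  expect_equal(resolution(c(1, 2, 3), rep(0.1, 3), c = 1.18), 11.8)
  # coincident peaks contribute zero
  expect_equal(resolution(c(1, 1), c(0.1, 0.1)), 0)
  expect_error(resolution(1, 0.1), "2 peaks")

  set.seed(12)
  t <- cumsum(runif(5, 0.5, 2))
  w <- runif(5, 0.05, 0.3)
  r0 <- resolution(t, w)
  # shift invariance
  expect_equal(resolution(t + 7.3, w), r0, tolerance = 1e-12)
  # common dilation of times and widths leaves resolution unchanged;
  # dilating times alone scales it linearly
  expect_equal(resolution(2 * t, 2 * w), r0, tolerance = 1e-12)
  expect_equal(resolution(2 * t, w), 2 * r0, tolerance = 1e-12)
  # widths doubled alone: halved
  expect_equal(resolution(t, 2 * w), r0 / 2, tolerance = 1e-12)
})

test_that("the 1-D sinusoid has the documented shape", {
  x <- seq(0, 1, length.out = 10000)
  f <- sinusoid_1d(x)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(sinusoid_1d(0), 0.5)
})

test_that("endpoint_objective directions and combos", {
  df <- data.frame(height = c(10, 50, 30), width = c(3, 1, 2),
                   snr = c(2, 8, 5))
  expect_equal(which.max(endpoint_objective(df, "height")), 2L)
  # width is minimized: narrowest peak wins
  expect_equal(which.max(endpoint_objective(df, "width")), 2L)
  expect_equal(which.max(endpoint_objective(df, "snr")), 2L)
  expect_equal(which.max(endpoint_objective(df, "snr",
                                            snr_direction = "minimize")), 1L)
  suppressMessages({
    c1 <- endpoint_objective(df, "combo1")
    c2 <- endpoint_objective(df, "combo2")
  })
  hs <- minmax_scale(df$height)
  ws <- minmax_scale(df$width)
  ss <- minmax_scale(df$snr)
  expect_equal(c1, hs + 1 / pmax(ws, 1e-3))
  expect_equal(c2, ss + c1)
  expect_error(endpoint_objective(df[, 1, drop = FALSE], "combo1"), "width")
})
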