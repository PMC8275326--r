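test_that("prior and interpolation behaviour of the posterior", {
  gp <- gp_new(sigma = 1.3, lengthscale = 0.25)
  p <- gp_posterior(gp, c(0.4, 0.7))
  expect_equal(p$mean, 0)
  expect_equal(p$variance, 1.3^2)

  # at an observed point with vanishing noise: mean = y, variance -> 0
  gp <- gp_new(noise = 1e-12)
  gp <- gp_add(gp, rbind(c(0.2, 0.8), c(0.6, 0.1)), c(1.5, -0.4))
  p <- gp_posterior(gp, c(0.2, 0.8))
  expect_equal(p$mean, 1.5, tolerance = 1e-6)
  expect_lt(p$variance, 1e-6)
})

test_that("posterior equals the dense linear-algebra oracle to 1e-8", {
  set.seed(7)
  for (rep in 1:10) {
    d <- sample(1:3, 1)
    n <- sample(2:20, 1)
    X <- matrix(runif(n * d), n, d)
    y <- runif(n, -1, 2)
    sigma <- runif(1, 0.5, 2)
    l <- runif(1, 0.1, 0.6)
    gp <- gp_add(gp_new(sigma, l, noise = 1e-6), X, y)
    xq <- runif(d)
    got <- gp_posterior(gp, xq)
    want <- oracle_gp_posterior(X, y, xq, sigma, l, 1e-6)
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    # variance compared at 1e-8 relative to the prior scale (interpolated
    # queries drive the absolute variance to ~0, where a pure relative
    # comparison is ill-posed)
    expect_lt(abs(got$variance - max(want$variance, 0)),
              1e-8 * max(1, gp$sigma^2))
  }
})

test_that("two-observation midpoint matches a hand-assembled 2x2 system", {
  gp <- gp_add(gp_new(1, 0.25, noise = 1e-6), rbind(0.2, 0.8), c(1, 2))
  got <- gp_posterior(gp, 0.5)
  want <- oracle_gp_posterior(rbind(0.2, 0.8), c(1, 2), 0.5, 1, 0.25, 1e-6)
  expect_equal(got$mean, want$mean, tolerance = 1e-10)
  expect_equal(got$variance, want$variance, tolerance = 1e-10)
})

test_that("UCB coefficient is non-decreasing in M and the bound is correct", {
  Ms <- 1:500
  b <- ucb_coefficient(Ms, 0.05)
  expect_true(all(diff(b) >= 0))
  expect_equal(b[1], sqrt(2 * log(pi^2 / (12 * 0.05))))

  # prior-only surrogate: ucb = B(M, eta) * sigma by direct substitution
  gp <- gp_new(sigma = 2)
  pol <- ucb_policy(0.05)
  u <- gp_ucb(gp, pol, 0.3)
  expect_identical(pol$M, 1L)
  expect_equal(u, 0 + ucb_coefficient(1, 0.05) * 2)

  # variance ~ 0 at an observed point: ucb ~ observed value
  gp2 <- gp_add(gp_new(noise = 1e-12), matrix(0.5), 0.9)
  u2 <- gp_ucb(gp2, pol, 0.5)
  expect_equal(u2, 0.9, tolerance = 1e-4)

  # same gp, same x, later M: ucb never decreases
  pol2 <- ucb_policy(0.05)
  gp3 <- gp_add(gp_new(), matrix(0.2), 0.4)
  u_early <- gp_ucb(gp3, pol2, 0.7)
  pol2$M <- 50L
  u_late <- gp_ucb(gp3, pol2, 0.7)
  expect_gte(u_late, u_early)
})

test_that("ill-conditioned kernel matrix gives advice to raise jitter", {
  gp <- gp_new(noise = 0)
  expect_error(gp_add(gp, rbind(0.5, 0.5), c(1, 1)), "jitter|noise")
})

test_that("refit recovers a known lengthscale within a factor of 2", {
  X <- matrix(seq(0, 1, length.out = 40))
  y <- oracle_gp_draw(X, sigma = 1, l = 0.2, seed = 11)
  gp <- gp_add(gp_new(sigma = 1, lengthscale = 0.25), X, y)
  fit <- gp_refit(gp)
  expect_gt(fit$lengthscale, 0.1)
  expect_lt(fit$lengthscale, 0.4)
  expect_gte(gp_log_marginal(fit), gp_log_marginal(gp) - 1e-6)
})

test_that("refit is idempotent under the fixed restart seed", {
  set.seed(3)
  gp <- gp_add(gp_new(), matrix(runif(8)), runif(8))
  f1 <- gp_refit(gp)
  f2 <- gp_refit(f1)
  expect_equal(f1$sigma, f2$sigma)
  expect_equal(f1$lengthscale, f2$lengthscale)
})

test_that("constant observations drive sigma toward its lower bound", {
  gp <- gp_add(gp_new(), matrix(seq(0.1, 0.9, length.out = 6)), rep(0, 6))
  fit <- gp_refit(gp)
  expect_lt(fit$sigma, 0.01)
})

test_that("fewer than 2 observations leaves hyperparameters untouched", {
  gp <- gp_add(gp_new(sigma = 1.5, lengthscale = 0.3), matrix(0.5), 1)
  expect_message(fit <- gp_refit(gp), "fewer than 2")
  expect_equal(fit$sigma, 1.5)
  expect_equal(fit$lengthscale, 0.3)
})
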