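test_that("EI and PI agree with numerical-integration oracles", {
  set.seed(31)
  for (rep in 1:5) {
    gp <- gp_add(gp_new(), matrix(runif(1)), runif(1, 0, 1))
    x <- runif(1)
    post <- gp_posterior(gp, x)
    mu <- post$mean
    sd <- sqrt(post$variance)
    best <- runif(1, -0.5, 1.5)
    z <- (mu - best) / sd
    ei <- (mu - best) * pnorm(z) + sd * dnorm(z)
    pi <- pnorm(z)
    expect_equal(ei, oracle_ei(mu, sd, best), tolerance = 1e-6)
    expect_equal(pi, oracle_pi(mu, sd, best), tolerance = 1e-6)
  }
})

test_that("batch_bo is reproducible and exhausts the budget exactly", {
  sw <- generate_sweep(sizes = c(4, 3, 2), seed = 2)
  for (acq in c("ts", "ei", "pi", "ucb")) {
    r1 <- batch_bo(sw$data, sw$space, "height", acquisition = acq,
                   batch = 3, budget = 9, seed = 7)
    r2 <- batch_bo(sw$data, sw$space, "height", acquisition = acq,
                   batch = 3, budget = 9, seed = 7)
    expect_identical(r1$history, r2$history)
    expect_equal(nrow(r1$history), 9)
    expect_false(any(duplicated(r1$history$config_index)))
    expect_true(all(diff(r1$history$best_so_far) >= 0))
  }
  # budget = initial size: only the random training set is evaluated
  r <- batch_bo(sw$data, sw$space, "height", acquisition = "ei",
                batch = 4, budget = 4, seed = 1)
  expect_equal(nrow(r$history), 4)
})

test_that("random baseline matches the hypergeometric success probability", {
  obj <- c(rep(0, 119), 1)  # unique optimum
  hits <- vapply(1:400, function(s)
    random_select(obj, 25, seed = s)$found_optimum, logical(1))
  # P(success) = 25/120 ~ 0.208; binomial SE over 400 trials ~ 0.02
  expect_gt(mean(hits), 25 / 120 - 0.065)
  expect_lt(mean(hits), 25 / 120 + 0.065)
  # full budget always finds the optimum
  expect_true(random_select(obj, 120, seed = 1)$found_optimum)
  expect_identical(random_select(obj, 10, seed = 3)$history,
                   random_select(obj, 10, seed = 3)$history)
})

test_that("LHS occupies one stratum per dimension and snaps levels", {
  sp <- config_space(param_continuous("flow_rate", 0.2, 2, "mL/min"),
                     param_continuous("injection_volume", 1, 50),
                     param_continuous("column_temperature", 25, 45),
                     param_continuous("absorbance_wavelength", 260, 285),
                     param_levels("solvent_ratio",
                                  c("65:35", "70:30", "75:25", "80:20")),
                     param_categorical("gradient",
                                       c("non-linear", "constant",
                                         "quick linear", "linear",
                                         "slow linear")))
  des <- lhs_sample(sp, 18, seed = 2)
  expect_equal(nrow(des), 18)
  U <- attr(des, "scaled")
  for (j in 1:6) {
    expect_setequal(floor(U[, j] * 18), 0:17)  # one sample per stratum
  }
  expect_true(all(des$flow_rate >= 0.2 & des$flow_rate <= 2))
  expect_true(all(des$injection_volume >= 1 & des$injection_volume <= 50))
  expect_true(all(des$solvent_ratio %in%
                    c("65:35", "70:30", "75:25", "80:20")))
  # reproducible under seed; n = 1 works
  expect_identical(des, lhs_sample(sp, 18, seed = 2))
  expect_equal(nrow(lhs_sample(sp, 1, seed = 1)), 1)
})

test_that("acquisitions beat random on average on an easy planted sweep", {
  sw <- generate_sweep(sizes = c(4, 3, 2), family = "unimodal", seed = 5)
  obj <- endpoint_objective(sw$data, "height")
  seeds <- 1:30
  rand <- mean(vapply(seeds, function(s)
    random_select(obj, 12, seed = s)$found_optimum, logical(1)))
  for (acq in c("ei", "ucb")) {
    acc <- mean(vapply(seeds, function(s)
      batch_bo(sw$data, sw$space, obj, acquisition = acq, batch = 4,
               budget = 12, seed = s)$found_optimum, logical(1)))
    expect_gt(acc, rand)
    expect_lt(acc, 1 + 1e-9)  # and below exhaustive search
  }
})
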