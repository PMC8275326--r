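# Conventional comparison strategies: batch-mode GP optimization over a
# finite candidate set with standard acquisitions (Thompson sampling, EI,
# PI, UCB), uniform random selection, and Latin hypercube sampling.

acq_scores <- function(gp, policy, Z, acquisition, incumbent) {
  post <- gp_posterior(gp, Z)
  mu <- post$mean
  sd <- sqrt(post$variance)
  switch(acquisition,
         ucb = {
           policy$M <- policy$M + nrow(Z)
           mu + ucb_coefficient(policy$M, policy$eta) * sd
         },
         ei = {
           z <- ifelse(sd > 0, (mu - incumbent) / sd, 0)
           out <- (mu - incumbent) * stats::pnorm(z) + sd * stats::dnorm(z)
           ifelse(sd > 0, out, pmax(mu - incumbent, 0))
         },
         pi = {
           ifelse(sd > 0, stats::pnorm((mu - incumbent) / sd),
                  as.numeric(mu > incumbent))
         },
         ts = {
           # exact joint posterior draw over the candidate set
           K <- kernel_eval(gp, Z, Z) + diag(1e-8 * gp$sigma^2, nrow(Z))
           if (gp_n(gp) > 0) {
             ks <- kernel_eval(gp, gp$X, Z)
             v <- backsolve(gp$L, ks, transpose = TRUE)
             K <- K - crossprod(v)
           }
           eg <- eigen(K, symmetric = TRUE)
           L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(Z))
           mu + as.numeric(L %*% stats::rnorm(nrow(Z)))
         },
         stop("unknown acquisition: ", acquisition))
}

#' Batch-mode GP optimization over a finite candidate set
#'
#' The standard comparison protocol: draw a random initial training set of
#' size `batch`, then repeatedly score every unused candidate with the
#' acquisition function, evaluate the top `batch`, refit the surrogate, and
#' stop when the evaluation budget is exhausted.
#'
#' @param data Candidate table (parameter + endpoint columns).
#' @param space A [config_space()] for the parameter columns.
#' @param objective Endpoint name or numeric objective vector (maximize),
#'   as in [fbo_optimize_discrete()].
#' @param acquisition One of `"ts"`, `"ei"`, `"pi"`, `"ucb"`.
#' @param batch Batch size = parallelism level = initial training size.
#'   Default 4.
#' @param budget Total evaluations (must be >= `batch`). Default 25.
#' @param seed Seed for the initial training draw (and TS draws).
#' @param eta UCB confidence parameter (UCB acquisition only).
#' @param sigma,lengthscale,noise,kernel Surrogate settings, see [gp_new()].
#' @param refit Refit hyperparameters after each batch. Default TRUE.
#' @return A list with `history` (data frame: eval, value, best_so_far,
#'   config_index), `found_optimum`, `n_to_optimum` (evaluations until the
#'   optimum was first requested, `NA` if never) and `best_value`.
#' @export
batch_bo <- function(data, space, objective = "height",
                     acquisition = c("ts", "ei", "pi", "ucb"),
                     batch = 4, budget = 25, seed = 1L, eta = 0.05,
                     sigma = 1, lengthscale = 0.25, noise = 1e-6,
                     kernel = "matern52", refit = TRUE) {
  acquisition <- match.arg(acquisition)
  obj <- if (is.character(objective))
    endpoint_objective(data, objective) else as.numeric(objective)
  n <- nrow(data)
  stopifnot(length(obj) == n, budget >= batch, n >= budget)
  cands <- candidate_set(space, data)
  Z <- cands$scaled
  gp <- gp_new(sigma, lengthscale, noise, kernel)
  policy <- ucb_policy(eta)
  chosen <- integer(0)
  with_local_seed(seed, {
    init <- sample.int(n, batch)
    chosen <- init
    gp <- gp_add(gp, Z[init, , drop = FALSE], obj[init])
    while (length(chosen) < budget) {
      if (refit && gp_n(gp) >= 2) gp <- gp_refit(gp)
      free <- setdiff(seq_len(n), chosen)
      scores <- acq_scores(gp, policy, Z[free, , drop = FALSE],
                           acquisition, incumbent = max(obj[chosen]))
      take <- free[order(-scores, free)][seq_len(min(batch,
                                                     budget - length(chosen)))]
      chosen <- c(chosen, take)
      gp <- gp_add(gp, Z[take, , drop = FALSE], obj[take])
    }
  })
  vals <- obj[chosen]
  opt <- which.max(obj)
  list(history = data.frame(eval = seq_along(chosen), value = vals,
                            best_so_far = cummax(vals),
                            config_index = chosen),
       found_optimum = opt %in% chosen,
       n_to_optimum = if (opt %in% chosen) match(opt, chosen) else NA_integer_,
       best_value = max(vals), acquisition = acquisition)
}

#' Uniform random selection baseline
#'
#' @param objective Numeric objective vector over the candidate rows.
#' @param budget Number of configurations to draw (without replacement).
#' @param seed Seed.
#' @return Same shape as [batch_bo()]'s return value.
#' @export
random_select <- function(objective, budget, seed = 1L) {
  n <- length(objective)
  stopifnot(budget <= n)
  chosen <- with_local_seed(seed, sample.int(n, budget))
  vals <- objective[chosen]
  opt <- which.max(objective)
  list(history = data.frame(eval = seq_along(chosen), value = vals,
                            best_so_far = cummax(vals),
                            config_index = chosen),
       found_optimum = opt %in% chosen,
       n_to_optimum = if (opt %in% chosen) match(opt, chosen) else NA_integer_,
       best_value = max(vals), acquisition = "random")
}

#' Latin hypercube sample over a search space
#'
#' Standard LHS: for each dimension the `n` samples occupy `n` distinct
#' strata of width `1/n`, placed uniformly at random within their stratum.
#' Finite (levels/categorical) dimensions are snapped to the nearest level.
#'
#' @param space A [config_space()].
#' @param n Number of samples.
#' @param seed Seed.
#' @return A data frame of `n` native configurations (one column per
#'   parameter), with the scaled design in attribute `"scaled"`.
#' @export
lhs_sample <- function(space, n, seed = 1L) {
  stopifnot(n >= 1)
  d <- space$d
  U <- with_local_seed(seed, {
    vapply(seq_len(d), function(j) {
      (sample.int(n) - stats::runif(n)) / n
    }, numeric(n))
  })
  if (n == 1L) U <- matrix(U, nrow = 1)
  rows <- lapply(seq_len(n), function(i) {
    cfg <- space_unscale(space, U[i, ])
    as.data.frame(cfg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scaled") <- U
  out
}
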