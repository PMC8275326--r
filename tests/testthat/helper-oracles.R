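# Independent oracles used to cross-check the implementation.  These are
# deliberately written as brute force / dense linear algebra, sharing no code
# with the package internals they verify.

# upper-hull membership by exhaustive pairwise chord tests: a point is on the
# frontier iff it is not dominated at its own depth (strictly larger UCB) and
# does not lie strictly below any chord between points on either side
oracle_frontier <- function(depth, ucb) {
  n <- length(depth)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (any(depth == depth[i] & ucb > ucb[i])) next
    below <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (depth[a] < depth[i] && depth[i] < depth[b]) {
          yl <- ucb[a] + (ucb[b] - ucb[a]) *
            (depth[i] - depth[a]) / (depth[b] - depth[a])
          if (ucb[i] < yl - 1e-12) below <- TRUE
        }
      }
    }
    keep[i] <- !below
  }
  which(keep)
}

# dense linear-algebra GP posterior per the closed form, assembled with
# explicit matrices and solve() (no Cholesky, no shared code)
oracle_matern52 <- function(r, sigma, l) {
  s <- sqrt(5) * r / l
  sigma^2 * (1 + s + s^2 / 3) * exp(-s)
}

oracle_gp_posterior <- function(X, y, xq, sigma, l, noise) {
  X <- as.matrix(X)
  xq <- as.numeric(xq)
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- oracle_matern52(sqrt(sum((X[i, ] - X[j, ])^2)), sigma, l)
  ks <- vapply(seq_len(n), function(i)
    oracle_matern52(sqrt(sum((X[i, ] - xq)^2)), sigma, l), numeric(1))
  Kinv <- solve(K + diag(noise, n))
  list(mean = drop(ks %*% Kinv %*% y),
       variance = drop(sigma^2 - ks %*% Kinv %*% ks))
}

# draw a function from a Matern-5/2 GP on given inputs (dense MVN draw)
oracle_gp_draw <- function(X, sigma, l, seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- oracle_matern52(sqrt(sum((X[i, ] - X[j, ])^2)), sigma, l)
  eg <- eigen(K + diag(1e-10, n), symmetric = TRUE)
  set.seed(seed)
  drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n)))
}

# EI / PI by direct numerical integration over the posterior predictive
oracle_ei <- function(mu, sd, best) {
  stats::integrate(function(y) pmax(y - best, 0) * stats::dnorm(y, mu, sd),
                   mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-10)$value
}

oracle_pi <- function(mu, sd, best) {
  stats::integrate(function(y) stats::dnorm(y, mu, sd),
                   best, mu + 12 * sd, rel.tol = 1e-10)$value
}

# tiny engine-state constructor for unit tests of the optimizer steps
make_engine <- function(d, f, k = 4, budget = 25, lookahead = 4, ...) {
  eval_fun <- function(node) {
    list(status = "ok", value = f(node$center), x_obs = node$center,
         config = NULL, index = NULL)
  }
  frontierBO:::new_engine_state(d, eval_fun, k, budget, lookahead,
                                eta = 0.05, sigma = 1, lengthscale = 0.25,
                                noise = 1e-6, kernel = "matern52",
                                refit = TRUE, refit_restarts = 5L,
                                refit_seed = 0L, max_iterations = 1000L,
                                lab = NULL, async = FALSE)
}
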