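# Gaussian-process surrogate with Matern 5/2 (default) or squared-exponential
# kernel, zero prior mean, fixed noise jitter.  The surrogate is a plain list;
# all update functions return a modified copy (functional style), with the
# Cholesky factor of the kernel matrix cached so repeated posterior queries
# are O(n^2).

#' Create a Gaussian-process surrogate
#'
#' The surrogate has zero prior mean and kernel amplitude `sigma^2`, so the
#' prior predictive at any point is `N(0, sigma^2)`.  Observations are assumed
#' noiseless up to a small jitter `noise` added to the kernel diagonal for
#' numerical stability.
#'
#' @param sigma Signal scale (kernel amplitude is `sigma^2`). Default 1.
#' @param lengthscale Kernel length scale. Default 0.25 (unit-hypercube inputs).
#' @param noise Noise variance added to the kernel diagonal (jitter).
#'   Default `1e-6`: replayed lab measurements are treated as noiseless.
#' @param kernel `"matern52"` (default) or `"rbf"`.
#' @return An object of class `fbo_gp`.
#' @export
gp_new <- function(sigma = 1, lengthscale = 0.25, noise = 1e-6,
                   kernel = c("matern52", "rbf")) {
  kernel <- match.arg(kernel)
  stopifnot(sigma > 0, lengthscale > 0, noise >= 0)
  gp <- list(sigma = sigma, lengthscale = lengthscale, noise = noise,
             kernel = kernel, X = NULL, y = numeric(0),
             L = NULL, alpha = NULL)
  class(gp) <- "fbo_gp"
  gp
}

#' @export
print.fbo_gp <- function(x, ...) {
  cat(sprintf("<fbo_gp> kernel=%s sigma=%.4g l=%.4g noise=%.2g n=%d\n",
              x$kernel, x$sigma, x$lengthscale, x$noise, gp_n(x)))
  invisible(x)
}

gp_n <- function(gp) if (is.null(gp$X)) 0L else nrow(gp$X)

# pairwise Euclidean distances between rows of A (n x d) and B (m x d)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

kernel_eval <- function(gp, A, B) {
  r <- cross_dist(A, B)
  if (gp$kernel == "matern52") {
    s <- sqrt(5) * r / gp$lengthscale
    gp$sigma^2 * (1 + s + s^2 / 3) * exp(-s)
  } else {
    gp$sigma^2 * exp(-r^2 / (2 * gp$lengthscale^2))
  }
}

# (re)build the Cholesky cache; signals a condition with advice when the
# kernel matrix is numerically singular at the current jitter.
gp_refresh <- function(gp) {
  n <- gp_n(gp)
  if (n == 0L) {
    gp$L <- NULL
    gp$alpha <- NULL
    return(gp)
  }
  K <- kernel_eval(gp, gp$X, gp$X) + diag(gp$noise, n)
  L <- tryCatch(chol(K), error = function(e) {
    stop("kernel matrix is ill-conditioned; raise the `noise` jitter ",
         "(currently ", format(gp$noise), ")", call. = FALSE)
  })
  gp$L <- L
  gp$alpha <- backsolve(L, backsolve(L, gp$y, transpose = TRUE))
  gp
}

#' Add observations to a surrogate
#'
#' @param gp An `fbo_gp`.
#' @param X Matrix of input points (rows) or a single numeric vector.
#' @param y Observed values, one per row of `X`.
#' @return The updated surrogate.
#' @export
gp_add <- function(gp, X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  gp$X <- if (is.null(gp$X)) X else rbind(gp$X, X)
  gp$y <- c(gp$y, as.numeric(y))
  gp_refresh(gp)
}

#' Posterior mean and variance
#'
#' Computes the closed-form GP posterior
#' \eqn{\mu(x) = k(x,X)(K+\sigma_n^2 I)^{-1} y} and
#' \eqn{v(x) = k(x,x) - k(x,X)(K+\sigma_n^2 I)^{-1} k(X,x)}.
#' With no observations this is the prior: mean 0, variance `sigma^2`.
#'
#' @param gp An `fbo_gp`.
#' @param x Query point(s): numeric vector (one point) or matrix of rows.
#' @return A list with numeric vectors `mean` and `variance` (clamped at 0).
#' @export
gp_posterior <- function(gp, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  n <- gp_n(gp)
  if (n == 0L) {
    return(list(mean = rep(0, nrow(x)), variance = rep(gp$sigma^2, nrow(x))))
  }
  ks <- kernel_eval(gp, gp$X, x)          # n x m
  mu <- drop(crossprod(ks, gp$alpha))
  v <- backsolve(gp$L, ks, transpose = TRUE)
  var <- gp$sigma^2 - colSums(v^2)
  list(mean = as.numeric(mu), variance = pmax(as.numeric(var), 0))
}

#' Log marginal likelihood of the observations
#'
#' @param gp An `fbo_gp` with at least one observation.
#' @return The log marginal likelihood (numeric scalar).
#' @export
gp_log_marginal <- function(gp) {
  n <- gp_n(gp)
  stopifnot(n >= 1L)
  -0.5 * sum(gp$y * gp$alpha) - sum(log(diag(gp$L))) - n / 2 * log(2 * pi)
}

#' Upper-confidence-bound policy
#'
#' The confidence coefficient follows the bound-based BO convention
#' \eqn{B(M,\eta) = \sqrt{2 \log(\pi^2 M^2 / (12\eta))}} where `M` counts the
#' UCB queries issued so far, so the bound widens slowly as more queries are
#' made.  `B` is non-decreasing in `M` for fixed `eta`.  The policy object is
#' an environment so the counter survives across calls.
#'
#' @param eta Confidence parameter in (0, 1). Default 0.05.
#' @return An environment of class `fbo_ucb_policy` with fields `eta`, `M`.
#' @export
ucb_policy <- function(eta = 0.05) {
  stopifnot(eta > 0, eta < 1)
  pol <- new.env(parent = emptyenv())
  pol$eta <- eta
  pol$M <- 0L
  class(pol) <- "fbo_ucb_policy"
  pol
}

#' @export
print.fbo_ucb_policy <- function(x, ...) {
  cat(sprintf("<fbo_ucb_policy> eta=%.3g M=%d B=%.4g\n",
              x$eta, x$M, ucb_coefficient(max(x$M, 1L), x$eta)))
  invisible(x)
}

#' UCB coefficient B(M, eta)
#' @param M Positive integer query count.
#' @param eta Confidence parameter.
#' @return Numeric coefficient.
#' @export
ucb_coefficient <- function(M, eta = 0.05) {
  sqrt(2 * log(pi^2 * M^2 / (12 * eta)))
}

#' Upper confidence bound at query points
#'
#' Returns `mean + B(M, eta) * sqrt(variance)` and advances the policy's
#' query counter by the number of points queried.
#'
#' @param gp An `fbo_gp`.
#' @param policy An `fbo_ucb_policy`.
#' @param x Query point(s): vector or matrix of rows.
#' @return Numeric vector of UCB values.
#' @export
gp_ucb <- function(gp, policy, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  post <- gp_posterior(gp, x)
  policy$M <- policy$M + nrow(x)
  b <- ucb_coefficient(policy$M, policy$eta)
  post$mean + b * sqrt(post$variance)
}

# run expr with a temporary RNG state seeded by `seed`, restoring the global
# state afterwards so internal randomized routines do not perturb user seeds
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Refit kernel hyperparameters by maximizing the log marginal likelihood
#'
#' Multi-restart L-BFGS-B over `log(sigma)` and `log(lengthscale)`.  The
#' incoming hyperparameters are always one of the starting points, so the
#' achieved log marginal likelihood never decreases.  Restart points are drawn
#' log-uniformly inside the bounds from a fixed internal seed, making the
#' refit deterministic and idempotent.
#'
#' @param gp An `fbo_gp` with at least 2 observations (fewer: returned
#'   unchanged with a message).
#' @param lower,upper Bounds for `c(sigma, lengthscale)`.
#' @param restarts Number of random restarts in addition to the incoming
#'   hyperparameters. Default 5.
#' @param seed Internal seed for the restart draws. Default 0.
#' @return The refitted surrogate.
#' @export
gp_refit <- function(gp, lower = c(1e-3, 1e-3), upper = c(10, 10),
                     restarts = 5L, seed = 0L) {
  n <- gp_n(gp)
  if (n < 2L) {
    message("gp_refit: fewer than 2 observations; keeping hyperparameters")
    return(gp)
  }
  nll <- function(par) {
    g <- gp
    g$sigma <- exp(par[1])
    g$lengthscale <- exp(par[2])
    g2 <- tryCatch(gp_refresh(g), error = function(e) NULL)
    if (is.null(g2)) return(1e10)
    ll <- gp_log_marginal(g2)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lo <- log(lower)
  hi <- log(upper)
  starts <- list(log(c(gp$sigma, gp$lengthscale)))
  extra <- with_local_seed(seed, {
    lapply(seq_len(restarts), function(i) lo + stats::runif(2) * (hi - lo))
  })
  starts <- c(starts, extra)
  best_par <- starts[[1]]
  best_val <- nll(best_par)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lo), hi), nll, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
  }
  gp$sigma <- exp(best_par[1])
  gp$lengthscale <- exp(best_par[2])
  gp_refresh(gp)
}
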