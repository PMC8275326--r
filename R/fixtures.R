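# Synthetic fixture generators.  These stand in for the instrument datasets
# the replayed-lab mode expects: full-factorial parameter sweeps with
# endpoint columns and a planted optimum (mass-spectrometry stand-in), and
# Gaussian-peak chromatogram peak lists with a closed-form resolution
# (liquid-chromatography stand-in).  Every fixture carries a machine-readable
# answer key so optimizer success is checkable without human inspection.

#' Generate a full-factorial parameter sweep with planted optima
#'
#' Builds the Cartesian grid over `sizes` ordered numeric levels per
#' parameter (defaults mimic a 4-parameter, 120-configuration instrument
#' sweep), evaluates a seeded response surface on the scaled grid, and
#' derives three endpoint columns from it: `height` (large is good), `width`
#' (small is good) and `snr`.  A tiny seeded jitter breaks ties so each
#' endpoint has a unique optimum.  Surface families:
#' \describe{
#'   \item{unimodal}{a single Gaussian bump centred on a random grid point;}
#'   \item{multimodal}{the same plus 2 decoy bumps of lower amplitude
#'     elsewhere (exercises escape from local optima);}
#'   \item{rugged}{multimodal plus small seeded observation noise.}
#' }
#'
#' @param sizes Integer vector of grid sizes per parameter.
#'   Default `c(5, 4, 3, 2)` (120 rows).
#' @param family `"unimodal"`, `"multimodal"` or `"rugged"`.
#' @param seed Seed controlling the optimum location, decoys, noise, jitter.
#' @param noise_sd Observation noise for the rugged family. Default 0.02.
#' @return A list with `data` (the sweep table: parameter columns `p1..pd`
#'   plus `height`, `width`, `snr`), `space` (the matching [config_space()]),
#'   `key` (answer key: per-endpoint optimum row and configuration) and
#'   `optimum_index` (planted optimum row).
#' @export
generate_sweep <- function(sizes = c(5, 4, 3, 2),
                           family = c("unimodal", "multimodal", "rugged"),
                           seed = 1L, noise_sd = 0.02) {
  family <- match.arg(family)
  stopifnot(length(sizes) >= 1, all(sizes >= 1), prod(sizes) >= 2)
  d <- length(sizes)
  levels <- lapply(sizes, function(s) seq_len(s))
  grid <- expand.grid(rev(levels))[, d:1, drop = FALSE]
  names(grid) <- paste0("p", seq_len(d))
  n <- nrow(grid)
  # scaled coordinates of each grid point
  Z <- vapply(seq_len(d), function(j) {
    if (sizes[j] == 1L) rep(0.5, n) else (grid[[j]] - 1) / (sizes[j] - 1)
  }, numeric(n))

  with_local_seed(seed, {
    opt_idx <- sample.int(n, 1)
    bump <- function(center, amp, width) {
      amp * exp(-colSums((t(Z) - center)^2) / (2 * width^2))
    }
    g <- bump(Z[opt_idx, ], 1, 0.35)
    if (family %in% c("multimodal", "rugged")) {
      for (b in 1:2) {
        decoy <- stats::runif(d)
        g <- g + bump(decoy, stats::runif(1, 0.4, 0.65),
                      stats::runif(1, 0.1, 0.2))
      }
      # keep the planted point the strict global optimum
      if (which.max(g) != opt_idx) {
        g[opt_idx] <- max(g) + 0.05
      }
    }
    if (family == "rugged") {
      g <- g + stats::rnorm(n, 0, noise_sd)
    }
    jit <- function() stats::runif(n, -1e-6, 1e-6)
    data <- cbind(grid, data.frame(
      height = 100 * g + jit(),
      width = 2 - 1.5 * (g - min(g)) / (max(g) - min(g)) + jit(),
      snr = 5 + 20 * g + jit()
    ))
  })

  space <- config_space(lapply(seq_len(d), function(j) {
    param_levels(paste0("p", j), seq_len(sizes[j]))
  }))
  key <- lapply(c(height = "height", width = "width", snr = "snr",
                  combo1 = "combo1", combo2 = "combo2"), function(ep) {
    i <- which.max(endpoint_objective(data, ep))
    list(row = i, config = as.list(grid[i, , drop = FALSE]))
  })
  list(data = data, space = space, key = key, optimum_index = opt_idx,
       family = family, seed = seed)
}

#' Generate a synthetic chromatogram peak list
#'
#' Peaks at (optionally jittered) regular elution-time spacings with given
#' half-height widths; the resolution of the constructed list is known in
#' closed form and returned alongside.  Optionally a densely sampled
#' Gaussian-mixture trace is included for end-to-end demos.
#'
#' @param n_peaks Number of peaks (>= 2). Default 3.
#' @param spacing Nominal gap between adjacent elution times. Default 1.
#' @param widths Half-height widths: scalar (recycled) or vector. Default 0.1.
#' @param seed Seed for the jitter draws.
#' @param jitter Relative jitter applied to the spacings (0 = regular grid).
#' @param t0 Elution time of the first peak. Default 1.
#' @param c Gaussian shape constant used for the reference resolution.
#' @param trace Also return a sampled Gaussian-mixture trace. Default FALSE.
#' @return A list with `peaks` (data frame `time`, `half_height_width`),
#'   `resolution` (closed-form value) and optionally `trace`.
#' @export
generate_chromatogram <- function(n_peaks = 3, spacing = 1, widths = 0.1,
                                  seed = 1L, jitter = 0, t0 = 1, c = 1.18,
                                  trace = FALSE) {
  stopifnot(n_peaks >= 2, spacing > 0, all(widths > 0), jitter >= 0)
  w <- rep_len(widths, n_peaks)
  gaps <- rep(spacing, n_peaks - 1)
  if (jitter > 0) {
    gaps <- with_local_seed(seed, {
      gaps * stats::runif(n_peaks - 1, 1 - jitter, 1 + jitter)
    })
  }
  times <- t0 + c(0, cumsum(gaps))
  rs <- sum(c * gaps / (w[-n_peaks] + w[-1]))
  out <- list(peaks = data.frame(time = times, half_height_width = w),
              resolution = rs, c = c)
  if (trace) {
    tt <- seq(times[1] - 3 * max(w), times[n_peaks] + 3 * max(w),
              length.out = 2000)
    # half-height width w corresponds to a Gaussian sd of w / (2 sqrt(2 ln 2))
    sds <- w / (2 * sqrt(2 * log(2)))
    y <- rowSums(vapply(seq_len(n_peaks), function(i) {
      exp(-(tt - times[i])^2 / (2 * sds[i]^2))
    }, numeric(length(tt))))
    out$trace <- data.frame(time = tt, intensity = y)
  }
  out
}
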