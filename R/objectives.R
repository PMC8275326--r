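# Endpoint scoring.  Raw instrument endpoints (peak height, peak width, SNR)
# are min-max scaled per column before being combined, so differently
# distributed endpoints contribute on a common [0,1] scale.  The optimizer
# always maximizes; endpoints whose good direction is "small" (peak width)
# enter negated or inverted.

#' Min-max scale a column to [0, 1]
#'
#' @param x Numeric vector with at least one value.
#' @return `(x - min) / (max - min)`.  A constant column is degenerate and
#'   returns all 0.5 with a warning.
#' @export
minmax_scale <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant column: min-max scaling is degenerate, returning 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Combined endpoint: scaled height plus inverse scaled width
#'
#' `height + 1/width` on scaled endpoints.  Because min-max scaling sends the
#' narrowest peak's width to exactly 0, the width is clamped below at `eps`
#' before inversion; clamping preserves the ranking (the narrowest peak still
#' scores highest on the width term).
#'
#' @param height_scaled,width_scaled Scaled endpoints in `[0,1]` (vectorized).
#' @param eps Division guard for the width term. Default `1e-3`.
#' @return Numeric combined score.
#' @export
combo1 <- function(height_scaled, width_scaled, eps = 1e-3) {
  clamped <- pmax(width_scaled, eps)
  if (any(width_scaled < eps))
    message(sprintf("combo1: %d width value(s) below eps=%g clamped",
                    sum(width_scaled < eps), eps))
  height_scaled + 1 / clamped
}

#' Combined endpoint: scaled SNR plus combo1
#'
#' @param snr_scaled Scaled SNR in `[0,1]` (vectorized).
#' @param combo1_value Value(s) from [combo1()].
#' @return `snr_scaled + combo1_value`.
#' @export
combo2 <- function(snr_scaled, combo1_value) {
  snr_scaled + combo1_value
}

#' Chromatographic resolution of a peak list
#'
#' Sum over adjacent peak pairs of `c * (t[i+1] - t[i]) / (w[i] + w[i+1])`,
#' where `t` are elution times and `w` half-height widths.  Larger values
#' mean more clearly separated adjacent peaks.  The constant `c` arises from
#' the Gaussian peak-shape assumption; the half-height convention gives
#' c = 1.18.
#'
#' @param times Strictly increasing elution times (>= 2 peaks).
#' @param widths Positive half-height widths, one per peak.
#' @param c Gaussian shape constant. Default 1.18.
#' @return The resolution (numeric scalar).
#' @export
resolution <- function(times, widths, c = 1.18) {
  if (length(times) < 2)
    stop("resolution is undefined for fewer than 2 peaks")
  stopifnot(length(widths) == length(times), all(widths > 0),
            all(diff(times) >= 0))
  n <- length(times)
  sum(c * diff(times) / (widths[-n] + widths[-1]))
}

#' The 1-D sinusoidal test function
#'
#' `f(x) = (sin(13x) * sin(27x) + 1) / 2` on `[0,1]`: multimodal, bounded in
#' `[0,1]`, with its global maximizer near x = 0.868.  The standard worked
#' example for the optimizer.
#'
#' @param x Numeric vector in `[0,1]`.
#' @return Function values.
#' @export
sinusoid_1d <- function(x) {
  0.5 * (sin(13 * x) * sin(27 * x) + 1)
}

#' Objective values for every row of an endpoint table
#'
#' Maps raw endpoint columns (`height`, `width`, `snr`) to a single
#' to-be-maximized objective per row.  Scaling is min-max over the full table
#' (replayed-dataset regime).  Directions: height is maximized; width is
#' minimized (exposed as the negated scaled width); the SNR direction is
#' ambiguous in practice and is configurable, maximizing by default.
#'
#' @param data Data frame with columns `height`, `width`, `snr` (only the
#'   columns the chosen endpoint needs are required).
#' @param endpoint One of `"height"`, `"width"`, `"snr"`, `"combo1"`,
#'   `"combo2"`.
#' @param snr_direction `"maximize"` (default) or `"minimize"`; under
#'   `"minimize"` the standalone SNR objective is negated and the combo2 SNR
#'   term becomes `1 - snr_scaled`.
#' @param eps Division guard passed to [combo1()].
#' @return Numeric vector, one objective value per row (maximize).
#' @export
endpoint_objective <- function(data,
                               endpoint = c("height", "width", "snr",
                                            "combo1", "combo2"),
                               snr_direction = c("maximize", "minimize"),
                               eps = 1e-3) {
  endpoint <- match.arg(endpoint)
  snr_direction <- match.arg(snr_direction)
  need <- switch(endpoint,
                 height = "height", width = "width", snr = "snr",
                 combo1 = c("height", "width"),
                 combo2 = c("height", "width", "snr"))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("endpoint table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  sc <- lapply(need, function(cl) minmax_scale(data[[cl]]))
  names(sc) <- need
  switch(endpoint,
         height = sc$height,
         width = -sc$width,
         snr = if (snr_direction == "maximize") sc$snr else -sc$snr,
         combo1 = combo1(sc$height, sc$width, eps),
         combo2 = {
           snr_term <- if (snr_direction == "maximize") sc$snr else 1 - sc$snr
           combo2(snr_term, combo1(sc$height, sc$width, eps))
         })
}
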