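# Search-space definitions and the bijection to the unit hypercube.
# Continuous parameters map affinely; finite level lists (numeric or
# categorical) map to equally spaced points in [0,1] in their listed order,
# first level -> 0, last -> 1.  All distance computations downstream happen
# in scaled space.

#' Define a continuous parameter
#' @param name Parameter name.
#' @param min,max Range bounds, `min < max`.
#' @param unit Unit label (documentation only).
#' @return A parameter definition.
#' @export
param_continuous <- function(name, min, max, unit = "") {
  stopifnot(is.character(name), min < max)
  structure(list(name = name, kind = "continuous", min = min, max = max,
                 unit = unit), class = "fbo_param")
}

#' Define a finite ordered-levels parameter
#' @param name Parameter name.
#' @param levels Non-empty vector of levels; order is fixed and meaningful.
#' @param unit Unit label.
#' @return A parameter definition.
#' @export
param_levels <- function(name, levels, unit = "") {
  stopifnot(is.character(name), length(levels) >= 1)
  structure(list(name = name, kind = "levels", levels = levels, unit = unit),
            class = "fbo_param")
}

#' Define a categorical parameter (embedded as ordered levels)
#'
#' Categorical settings are numerically encoded as equally spaced points in
#' the order listed; no one-hot embedding is used.
#' @inheritParams param_levels
#' @return A parameter definition.
#' @export
param_categorical <- function(name, levels, unit = "") {
  p <- param_levels(name, levels, unit)
  p$kind <- "categorical"
  p
}

#' Assemble a search space
#' @param ... Parameter definitions from [param_continuous()],
#'   [param_levels()], [param_categorical()] (or a single list of them).
#' @return An object of class `fbo_space`.
#' @export
config_space <- function(...) {
  params <- list(...)
  if (length(params) == 1L && !inherits(params[[1]], "fbo_param"))
    params <- params[[1]]
  stopifnot(length(params) >= 1,
            all(vapply(params, inherits, logical(1), "fbo_param")))
  names(params) <- vapply(params, function(p) p$name, character(1))
  structure(list(params = params, d = length(params)), class = "fbo_space")
}

#' @export
print.fbo_space <- function(x, ...) {
  cat(sprintf("<fbo_space> %d parameters\n", x$d))
  for (p in x$params) {
    desc <- if (p$kind == "continuous")
      sprintf("[%g, %g]", p$min, p$max)
    else paste(p$levels, collapse = ", ")
    cat(sprintf("  %-20s %-11s %s %s\n", p$name, p$kind, desc, p$unit))
  }
  invisible(x)
}

scale_one <- function(p, v) {
  if (p$kind == "continuous") {
    v <- as.numeric(v)
    if (is.na(v) || v < p$min || v > p$max)
      stop(sprintf("value %s out of range [%g, %g] for parameter '%s'",
                   format(v), p$min, p$max, p$name))
    (v - p$min) / (p$max - p$min)
  } else {
    i <- match(as.character(v), as.character(p$levels))
    if (is.na(i))
      stop(sprintf("value '%s' is not a level of parameter '%s'", v, p$name))
    L <- length(p$levels)
    if (L == 1L) 0.5 else (i - 1) / (L - 1)
  }
}

unscale_one <- function(p, z) {
  if (p$kind == "continuous") {
    p$min + z * (p$max - p$min)
  } else {
    L <- length(p$levels)
    i <- if (L == 1L) 1L else round(z * (L - 1)) + 1L
    p$levels[[min(max(i, 1L), L)]]
  }
}

#' Map a native configuration to the unit hypercube
#'
#' @param space An `fbo_space`.
#' @param config Named list / vector / one-row data frame of native values.
#' @return Numeric vector in `[0,1]^d`, in space parameter order.
#' @export
space_scale <- function(space, config) {
  config <- as.list(config)
  vapply(space$params, function(p) {
    if (!p$name %in% names(config))
      stop(sprintf("configuration is missing parameter '%s'", p$name))
    scale_one(p, config[[p$name]])
  }, numeric(1))
}

#' Map a unit-hypercube point back to native values
#'
#' Exact inverse of [space_scale()] for levels/categorical parameters; for
#' continuous parameters the affine inverse.  Off-grid coordinates of finite
#' parameters snap to the nearest level.
#'
#' @param space An `fbo_space`.
#' @param z Numeric vector in `[0,1]^d`.
#' @return Named list of native values.
#' @export
space_unscale <- function(space, z) {
  stopifnot(length(z) == space$d)
  out <- mapply(function(p, zi) unscale_one(p, zi), space$params, z,
                SIMPLIFY = FALSE)
  names(out) <- names(space$params)
  out
}

#' Build a finite candidate set with one-use bookkeeping
#'
#' Each row of `data` (restricted to the space's parameter columns) is scaled
#' to the unit hypercube once; assignment marks candidates used so that no
#' configuration is ever evaluated twice in a run.
#'
#' @param space An `fbo_space`.
#' @param data Data frame with one column per parameter (extra endpoint
#'   columns are carried along untouched).
#' @return A mutable object of class `fbo_candidates`.
#' @export
candidate_set <- function(space, data) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  scaled <- t(apply(data[names(space$params)], 1, function(row) {
    space_scale(space, as.list(row))
  }))
  if (space$d == 1L) scaled <- matrix(as.numeric(scaled), ncol = 1)
  cs <- new.env(parent = emptyenv())
  cs$space <- space
  cs$data <- data
  cs$scaled <- scaled
  cs$used <- rep(FALSE, nrow(data))
  class(cs) <- "fbo_candidates"
  cs
}

#' @export
print.fbo_candidates <- function(x, ...) {
  cat(sprintf("<fbo_candidates> %d configurations (%d used)\n",
              nrow(x$data), sum(x$used)))
  invisible(x)
}

#' Assign the nearest unused candidate to an interval center
#'
#' Euclidean distance in scaled space; equidistant ties are broken by row
#' order in the input data.  The returned candidate is marked used.
#'
#' @param cands An `fbo_candidates`.
#' @param center Numeric vector in `[0,1]^d`.
#' @return `NULL` if every candidate is used, else a list with `index`
#'   (row number), `config` (native one-row data frame) and `scaled` coords.
#' @export
assign_center <- function(cands, center) {
  free <- which(!cands$used)
  if (length(free) == 0L) return(NULL)
  d2 <- colSums((t(cands$scaled[free, , drop = FALSE]) - center)^2)
  i <- free[which.min(d2)]   # which.min takes the first -> row-order ties
  cands$used[i] <- TRUE
  list(index = i,
       config = cands$data[i, names(cands$space$params), drop = FALSE],
       scaled = cands$scaled[i, ])
}
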