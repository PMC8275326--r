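# Save-state workflow for live closed-loop use: the optimizer's decisions
# are deterministic functions of the settings and the evaluated history, so
# the state file only stores the space, the settings, the (configuration,
# value) pairs obtained so far, and the pending suggestions.  `fbo_suggest()`
# replays the algorithm against the recorded results and halts at the first
# request with no recorded outcome — those requests are the next batch.

space_to_list <- function(space) {
  lapply(space$params, function(p) {
    if (p$kind == "continuous")
      list(name = p$name, kind = p$kind, min = p$min, max = p$max,
           unit = p$unit)
    else list(name = p$name, kind = p$kind, levels = as.list(p$levels),
              unit = p$unit)
  })
}

space_from_list <- function(lst) {
  config_space(lapply(lst, function(p) {
    if (p$kind == "continuous")
      param_continuous(p$name, p$min, p$max, p$unit %||% "")
    else if (p$kind == "categorical")
      param_categorical(p$name, unlist(p$levels), p$unit %||% "")
    else param_levels(p$name, unlist(p$levels), p$unit %||% "")
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_key <- function(space, config) {
  paste(format(round(space_scale(space, config), 10), trim = TRUE,
               scientific = FALSE), collapse = "|")
}

#' Initialize a save-state for live closed-loop optimization
#'
#' @param space A [config_space()].
#' @param k Parallelism level. Default 3.
#' @param budget Total evaluation budget. Default 25.
#' @param lookahead,eta,sigma,lengthscale,noise,kernel,refit Optimizer and
#'   surrogate settings (see [fbo_optimize()]).
#' @return An object of class `fbo_savestate`.
#' @export
fbo_state_new <- function(space, k = 3, budget = 25, lookahead = 4,
                          eta = 0.05, sigma = 1, lengthscale = 0.25,
                          noise = 1e-6, kernel = "matern52", refit = TRUE) {
  st <- list(version = 1L,
             space = space,
             settings = list(k = k, budget = budget, lookahead = lookahead,
                             eta = eta, sigma = sigma,
                             lengthscale = lengthscale, noise = noise,
                             kernel = kernel, refit = refit),
             history = list(),   # algorithm-requested (config, value) pairs
             extra = list(),     # historical uploads: condition the GP only
             pending = list())   # suggested configs awaiting results
  class(st) <- "fbo_savestate"
  st
}

#' @export
print.fbo_savestate <- function(x, ...) {
  cat(sprintf("<fbo_savestate> %d evaluated, %d historical, %d pending\n",
              length(x$history), length(x$extra), length(x$pending)))
  invisible(x)
}

#' Write a save-state file (JSON)
#' @param state An `fbo_savestate`.
#' @param path File path.
#' @return `state`, invisibly.
#' @export
fbo_state_write <- function(state, path) {
  out <- state
  out$space <- space_to_list(state$space)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(state)
}

#' Read a save-state file
#' @param path File path written by [fbo_state_write()].
#' @return An `fbo_savestate`.
#' @export
fbo_state_read <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  st <- list(version = lst$version %||% 1L,
             space = space_from_list(lst$space),
             settings = lapply(lst$settings, function(v) v),
             history = lst$history %||% list(),
             extra = lst$extra %||% list(),
             pending = lst$pending %||% list())
  class(st) <- "fbo_savestate"
  st
}

# replay the deterministic algorithm against the recorded results; returns
# the engine state (possibly awaiting results, with suggestions collected)
replay_engine <- function(state) {
  space <- state$space
  s <- state$settings
  results <- new.env(parent = emptyenv())
  for (h in state$history) {
    key <- config_key(space, h$config)
    results[[key]] <- c(results[[key]] %||% numeric(0), h$value)
  }
  eval_fun <- function(node) {
    cfg <- space_unscale(space, node$center)
    key <- config_key(space, cfg)
    vals <- results[[key]] %||% numeric(0)
    if (length(vals) == 0L)
      return(list(status = "unknown", config = cfg))
    results[[key]] <- vals[-1L]
    list(status = "ok", value = vals[1L], x_obs = node$center,
         config = cfg, index = NULL)
  }
  est <- new_engine_state(space$d, eval_fun, s$k, s$budget, s$lookahead,
                          s$eta, s$sigma, s$lengthscale, s$noise, s$kernel,
                          isTRUE(s$refit), 5L, 0L, 1000L, NULL, FALSE)
  # historical uploads condition the surrogate but never pre-grow the tree:
  # the search still starts at the center of the hyperrectangle
  for (h in state$extra) {
    est$gp <- gp_add(est$gp, space_scale(space, h$config), h$value)
  }
  engine_run(est)
  est
}

#' Suggest the next batch of configurations
#'
#' Replays the deterministic optimizer over the recorded results and returns
#' the first batch of requested-but-unevaluated configurations (at most `k`).
#' An empty suggestion set means the budget is exhausted.
#'
#' @param state An `fbo_savestate`.
#' @return A list with `suggestions` (data frame of native configurations)
#'   and `state` (with its `pending` field replaced by the suggestions).
#' @export
fbo_suggest <- function(state) {
  est <- replay_engine(state)
  sugg <- lapply(est$suggestions, function(s) s$config)
  df <- if (length(sugg) == 0L) NULL else {
    out <- do.call(rbind, lapply(sugg, function(cfg)
      as.data.frame(cfg, stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  state$pending <- sugg
  list(suggestions = df, state = state, finished = !isTRUE(est$awaiting),
       evaluations = est$N, best_value = est$nu_max,
       best_config = est$incumbent_config)
}

#' Ingest experiment results into a save-state
#'
#' Results matching a pending suggestion extend the evaluated history;
#' results for configurations that were never suggested are accepted with a
#' warning as historical data (they condition the surrogate but do not grow
#' the partition tree).
#'
#' @param state An `fbo_savestate`.
#' @param results Data frame with one column per space parameter plus a
#'   `value` column.
#' @return The updated `fbo_savestate`.
#' @export
fbo_ingest <- function(state, results) {
  stopifnot(is.data.frame(results), "value" %in% names(results))
  space <- state$space
  pend_keys <- vapply(state$pending, function(p)
    config_key(space, p$config %||% p), character(1))
  for (i in seq_len(nrow(results))) {
    cfg <- as.list(results[i, setdiff(names(results), "value"), drop = FALSE])
    rec <- list(config = cfg, value = results$value[i])
    key <- config_key(space, cfg)
    j <- match(key, pend_keys)
    if (is.na(j)) {
      warning("result for a non-suggested configuration accepted as ",
              "historical data: ", key)
      state$extra[[length(state$extra) + 1L]] <- rec
    } else {
      state$history[[length(state$history) + 1L]] <- rec
      state$pending <- state$pending[-j]
      pend_keys <- pend_keys[-j]
    }
  }
  state
}
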