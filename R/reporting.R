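# Reporting utilities: run summaries, success-rate tables, simple-regret
# traces, and plain-text diagnostic exports (tree snapshots, frontier logs,
# best-so-far curves).

#' Summary statistics of a success-rate table
#'
#' Given success probabilities (in percent) of a set of optimization
#' strategies, returns the mean, median, sample standard deviation and
#' maximum.  Used to summarize benchmark tables of baseline success rates.
#'
#' @param x Numeric vector or matrix/data frame of success percentages.
#' @param digits Rounding applied to the summaries (default 1, matching the
#'   precision such tables are usually reported at).
#' @return A list with `mean`, `median`, `sd`, `max`, `n`.
#' @export
summarize_success_table <- function(x, digits = 1) {
  v <- as.numeric(as.matrix(x))
  stopifnot(length(v) >= 1, !anyNA(v))
  list(mean = round(mean(v), digits),
       median = round(stats::median(v), digits),
       sd = round(stats::sd(v), digits),
       max = round(max(v), digits),
       n = length(v))
}

#' Load the bundled baseline success-rate reference table
#'
#' Success probabilities (percent) of conventional batch-BO strategies
#' (TS, EI, PI, UCB, random) for five spectral-quality endpoints on two
#' mass-spectrometry parameter-sweep benchmark datasets, as distributed with
#' the package for the reporting utilities.
#'
#' @return A data frame with columns `dataset`, `algorithm`, `endpoint`,
#'   `success_pct`.
#' @export
baseline_success_reference <- function() {
  path <- system.file("extdata", "maldi_baseline_success.csv",
                      package = "frontierBO", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simple-regret trace of a run history
#'
#' @param history A run history with a `best_so_far` column.
#' @param f_max The true optimum value (supremum of the objective).
#' @return Numeric vector `f_max - best_so_far`, non-increasing.
#' @export
regret_trace <- function(history, f_max) {
  f_max - history$best_so_far
}

#' Write run artifacts as delimited text
#'
#' Exports the evaluation history, the best-so-far curve, a tree snapshot
#' and the frontier log of an optimizer result into a directory.
#'
#' @param result An `fbo_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_run <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(result$history, "history.csv")
  w(result$history[, c("eval", "best_so_far")], "best_so_far.csv")
  w(tree_df(result$tree), "tree.csv")
  if (!is.null(result$frontier_log)) w(result$frontier_log, "frontier.csv")
  writeLines(tree_to_json(result$tree), file.path(dir, "tree.json"))
  paths <- c(paths, file.path(dir, "tree.json"))
  summary <- data.frame(best_value = result$best_value,
                        evaluations = result$evaluations,
                        iterations = result$iterations)
  if (!is.null(result$best_config))
    summary <- cbind(summary,
                     as.data.frame(result$best_config,
                                   stringsAsFactors = FALSE))
  w(summary, "summary.csv")
  invisible(paths)
}

#' Plot a best-so-far curve
#' @param history Run history with `eval` and `best_so_far` columns.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_best_so_far <- function(history, ...) {
  graphics::plot(history$eval, history$best_so_far, type = "s",
                 xlab = "evaluations", ylab = "best observed value", ...)
  invisible(NULL)
}

#' Plot a partition-tree snapshot (1-D runs)
#'
#' Nodes are placed at their interval centers against tree depth, mirroring
#' the standard visualization of the division scheme.
#' @param tree An `fbo_tree` with `d = 1`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_tree_1d <- function(tree, ...) {
  stopifnot(tree$d == 1L)
  df <- tree_df(tree)
  graphics::plot(df$c1, df$depth, ylim = rev(range(df$depth)),
                 pch = ifelse(df$value_kind == "gt", 19, 1),
                 xlab = "x", ylab = "depth", ...)
  invisible(NULL)
}
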