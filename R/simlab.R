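# Simulated cloud laboratory: a k-slot job queue under discrete-event
# virtual time, plus a ground-truth oracle that replays a tabulated dataset.
# The queue models the lab-side constraint that at most k experiments run
# simultaneously; per-job durations come from a configurable latency model.

#' Create a virtual lab queue
#'
#' @param k Number of simultaneous experiment slots (threads).
#' @param latency Either a single number (constant per-job duration, default
#'   1 virtual time unit) or a function `f(n)` returning `n` durations (e.g.
#'   [latency_lognormal()]).
#' @return A mutable object of class `fbo_lab`.
#' @export
lab_queue <- function(k, latency = 1) {
  stopifnot(k >= 1)
  lab <- new.env(parent = emptyenv())
  lab$k <- as.integer(k)
  lab$latency <- if (is.function(latency)) latency
                 else function(n) rep(as.numeric(latency), n)
  lab$free <- rep(0, k)     # next free virtual time per slot
  lab$now <- 0
  lab$jobs <- list()
  lab$next_id <- 1L
  class(lab) <- "fbo_lab"
  lab
}

#' @export
print.fbo_lab <- function(x, ...) {
  cat(sprintf("<fbo_lab> k=%d jobs=%d now=%.3g\n",
              x$k, length(x$jobs), x$now))
  invisible(x)
}

#' Seeded log-normal latency model
#'
#' Returns a latency function for [lab_queue()] that draws per-job durations
#' from a log-normal distribution using an internal seeded stream (the global
#' RNG state is untouched).
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @param seed Seed of the internal stream.
#' @return A function `f(n)` returning `n` durations.
#' @export
latency_lognormal <- function(meanlog = 0, sdlog = 0.5, seed = 1L) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  function(n) {
    counter$i <- counter$i + 1L
    with_local_seed(seed + counter$i, stats::rlnorm(n, meanlog, sdlog))
  }
}

#' Submit jobs to the lab queue
#'
#' Jobs are admitted FIFO and start as slots free; at most `k` run at any
#' virtual time.  Submission happens at the queue's current virtual time; the
#' barrier semantics of the optimizer advance the clock to the completion of
#' the batch.
#'
#' @param lab An `fbo_lab`.
#' @param n Number of jobs to submit (ids auto-assigned), or
#' @param ids Explicit job identifiers (duplicates are rejected).
#' @return Data frame with `id`, `submitted`, `start`, `done` per job.
#' @export
lab_submit <- function(lab, n = NULL, ids = NULL) {
  if (is.null(ids)) {
    stopifnot(!is.null(n), n >= 1)
    ids <- seq.int(lab$next_id, length.out = n)
  }
  existing <- vapply(lab$jobs, function(j) j$id, integer(1))
  if (anyDuplicated(c(existing, ids)))
    stop("duplicate job identifier(s): ",
         paste(intersect(existing, ids), collapse = ", "))
  n <- length(ids)
  durations <- lab$latency(n)
  out <- data.frame(id = as.integer(ids), submitted = lab$now,
                    start = NA_real_, done = NA_real_)
  for (i in seq_len(n)) {
    slot <- which.min(lab$free)
    start <- max(lab$now, lab$free[slot])
    done <- start + durations[i]
    lab$free[slot] <- done
    out$start[i] <- start
    out$done[i] <- done
    lab$jobs[[length(lab$jobs) + 1L]] <-
      list(id = out$id[i], submitted = lab$now, start = start, done = done,
           duration = durations[i])
  }
  lab$next_id <- max(c(lab$next_id, ids + 1L))
  lab$now <- max(out$done)  # barrier: wait for the whole batch
  out
}

#' Job statuses at a virtual time
#'
#' @param lab An `fbo_lab`.
#' @param t Virtual time (default: the queue's current clock).
#' @return Data frame of jobs with a `status` column
#'   (`QUEUED`/`RUNNING`/`DONE`).
#' @export
lab_status <- function(lab, t = lab$now) {
  if (length(lab$jobs) == 0L)
    return(data.frame(id = integer(0), status = character(0)))
  df <- do.call(rbind, lapply(lab$jobs, function(j)
    data.frame(id = j$id, submitted = j$submitted, start = j$start,
               done = j$done)))
  df$status <- ifelse(df$done <= t, "DONE",
                      ifelse(df$start <= t, "RUNNING", "QUEUED"))
  df
}

#' Exact endpoint lookup for a tabulated configuration
#'
#' Replayed-lab ground truth: the endpoints of a submitted configuration are
#' fetched from the dataset row whose parameter values match exactly.  A
#' missing configuration is a hard error — it indicates a bug in the
#' center-to-candidate mapping, which guarantees membership.
#'
#' @param data Dataset with parameter and endpoint columns.
#' @param space The [config_space()] naming the parameter columns.
#' @param config Named list of native parameter values.
#' @return The matching row of `data` (one-row data frame).
#' @export
oracle_lookup <- function(data, space, config) {
  config <- as.list(config)
  hit <- rep(TRUE, nrow(data))
  for (p in space$params) {
    v <- config[[p$name]]
    if (is.null(v)) stop("configuration is missing parameter '", p$name, "'")
    col <- data[[p$name]]
    hit <- hit & if (is.numeric(col))
      abs(col - as.numeric(v)) < 1e-9 else as.character(col) == as.character(v)
  }
  i <- which(hit)
  if (length(i) == 0L)
    stop("configuration not found in dataset (mapping bug?): ",
         paste(sprintf("%s=%s", names(config), unlist(config)), collapse = ", "))
  data[i[1L], , drop = FALSE]
}

#' Makespan of a job list under k slots
#'
#' Greedy FIFO schedule: each job takes the earliest free slot.  With `k = 1`
#' the makespan is the sum of durations; it is non-increasing in `k`.
#'
#' @param durations Numeric vector of per-job durations, in submission order.
#' @param k Number of slots.
#' @return Total virtual time to complete all jobs.
#' @export
elapsed_virtual_time <- function(durations, k) {
  stopifnot(k >= 1, all(durations >= 0))
  free <- rep(0, k)
  for (d in durations) {
    slot <- which.min(free)
    free[slot] <- free[slot] + d
  }
  max(free)
}
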