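#' Build a task specification
#'
#' A self-contained unit of work for the worker pool: an id, a function, a
#' closed-over payload, and the substream seed that supplies every bit of
#' the task's randomness.  Because randomness is keyed to the task id and
#' never to worker identity or timing, results are bit-identical for any
#' worker count.
#'
#' @param task_id Unique character id, conventionally
#'   `"epoch/branch/stage"`.
#' @param fun Function of one argument (the payload).
#' @param payload Arbitrary self-contained input object.
#' @param seed Integer substream seed (see [derive_seed()]).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task_id, fun, payload = NULL, seed = 1L) {
  stopifnot(is.character(task_id), length(task_id) == 1, is.function(fun))
  structure(list(task_id = task_id, fun = fun, payload = payload,
                 seed = as.integer(seed)),
            class = "task_spec")
}

#' Run a batch of tasks over a bounded worker pool
#'
#' Tasks are claimed in submission (first come, first served) order.  A
#' task that raises an error is recorded as a failed result; the batch
#' still drains.  The result mapping is bit-identical for any `n_workers`
#' because each task derives its randomness from its own substream seed.
#'
#' @param tasks List of [task_spec()]s with unique ids.
#' @param n_workers Worker count (>= 1); values above 1 fork via
#'   [parallel::mclapply()].
#' @return Named list keyed by task id; each element has `ok` (logical)
#'   and either `value` or `error` (the condition message).
#' @export
run_tasks <- function(tasks, n_workers = 1L) {
  n_workers <- as.integer(n_workers)
  stopifnot(n_workers >= 1L)
  ids <- vapply(tasks, function(t) t$task_id, character(1))
  if (anyDuplicated(ids)) stop("task ids must be unique", call. = FALSE)
  worker <- function(t) {
    tryCatch(list(ok = TRUE, value = with_substream(t$seed, t$fun(t$payload))),
             error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  res <- if (n_workers == 1L || length(tasks) <= 1L) {
    lapply(tasks, worker)
  } else {
    parallel::mclapply(tasks, worker, mc.cores = n_workers, mc.preschedule = TRUE)
  }
  # a fork-level failure (not a task error) surfaces as a try-error element
  for (k in seq_along(res)) {
    if (!is.list(res[[k]]) || is.null(res[[k]]$ok)) {
      res[[k]] <- worker(tasks[[k]])
    }
  }
  names(res) <- ids
  res
}
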