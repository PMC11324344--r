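# Methods for the binder_evolution result object.

#' @export
print.binder_evolution <- function(x, ...) {
  sch <- x$config$schedule
  cat(sprintf("<binder_evolution> %d epoch(s) run (%d scheduled, %d restrained), %s-width DAG\n",
              x$epochs_run, sch$total_epochs, sch$restrained_epochs, sch$width_mode))
  cat(sprintf("  nodes: %d  (active in last layer: %d)%s\n",
              length(x$dag$nodes),
              length(active_ids(x$dag, length(x$dag$epochs))),
              if (x$stopped_early) "  [stopped early: all lineages failed]" else ""))
  fin <- x$trajectory[x$trajectory$epoch == max(x$trajectory$epoch), ]
  cat("  final mean scores:\n")
  for (i in seq_len(nrow(fin))) {
    cat(sprintf("    %-20s %10.4f\n", fin$scorer[i], fin$mean_score[i]))
  }
  invisible(x)
}

#' Summarize an optimization run
#'
#' Reports the best final candidate per scorer, the score change from the
#' root, and counts of retained/pruned/failed nodes.
#'
#' @param object A `binder_evolution`.
#' @param ... Unused.
#' @return A list of class `summary.binder_evolution`.
#' @export
summary.binder_evolution <- function(object, ...) {
  dag <- object$dag
  statuses <- vapply(dag$nodes, function(n) n$status, character(1))
  last <- active_ids(dag, length(dag$epochs))
  root_avg <- dag$nodes[["0-0"]]$scores$averages
  best <- NULL
  if (length(last) > 0) {
    ref <- names(root_avg)[1]
    vals <- vapply(last, function(i) dag$nodes[[i]]$scores$averages[[ref]], numeric(1))
    bid <- last[which.min(vals)]
    best <- list(node_id = bid,
                 averages = dag$nodes[[bid]]$scores$averages,
                 mutations_from_root = rev(collect_mutations(dag, bid)),
                 sequence = binder_sequence(dag$nodes[[bid]]$complex))
  }
  structure(list(epochs_run = object$epochs_run,
                 stopped_early = object$stopped_early,
                 n_nodes = length(dag$nodes),
                 status_counts = table(statuses),
                 root_averages = root_avg,
                 best = best),
            class = "summary.binder_evolution")
}

collect_mutations <- function(dag, node_id) {
  out <- character(0)
  cur <- node_id
  while (!is.null(cur)) {
    out <- c(out, vapply(dag$nodes[[cur]]$mutations, format_mutation, character(1)))
    cur <- dag$nodes[[cur]]$parent_id
  }
  out
}

#' @export
print.summary.binder_evolution <- function(x, ...) {
  cat(sprintf("Optimization: %d epoch(s)%s, %d node(s)\n", x$epochs_run,
              if (x$stopped_early) " (stopped early)" else "", x$n_nodes))
  print(x$status_counts)
  cat("root averages:\n"); print(round(x$root_averages, 4))
  if (!is.null(x$best)) {
    cat(sprintf("best final candidate: %s\n", x$best$node_id))
    print(round(x$best$averages, 4))
    if (length(x$best$mutations_from_root) > 0) {
      cat("mutations from root:", paste(x$best$mutations_from_root, collapse = ", "), "\n")
    } else {
      cat("no mutations retained (root carried through)\n")
    }
  }
  invisible(x)
}

#' @export
as.data.frame.binder_evolution <- function(x, ...) {
  x$trajectory
}

#' Plot score trajectories of a run
#'
#' One line per scorer: the mean average score over the active nodes of
#' each epoch layer.  A dotted vertical line marks the switch from the
#' restrained to the unrestrained phase, where lifting the restraints lets
#' the interface relax.
#'
#' @param x A `binder_evolution`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.binder_evolution <- function(x, ...) {
  tr <- x$trajectory
  scorers <- unique(tr$scorer)
  epochs <- sort(unique(tr$epoch))
  m <- sapply(scorers, function(s) {
    tr$mean_score[tr$scorer == s][order(tr$epoch[tr$scorer == s])]
  })
  m <- matrix(m, nrow = length(epochs), dimnames = list(NULL, scorers))
  graphics::matplot(epochs, m, type = "b", pch = seq_along(scorers), lty = 1,
                    xlab = "epoch", ylab = "mean score (lower is better)", ...)
  rs <- x$config$schedule$restrained_epochs
  if (rs > 0 && rs < max(epochs)) {
    graphics::abline(v = rs + 0.5, lty = 3)
    graphics::mtext("restraints lifted", at = rs + 0.5, side = 3, cex = 0.7)
  }
  graphics::legend("topright", legend = scorers, pch = seq_along(scorers),
                   col = seq_along(scorers), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
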