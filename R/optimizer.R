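# The epoch loop: branch, mutate, sample, score, prune, manage DAG width.
# Every stochastic stage draws from a substream keyed by (epoch, node,
# branch, stage), so a run is a pure function of (config, seed) and is
# invariant to worker scheduling.

new_node <- function(node_id, parent_id, complex, mutations,
                     status = "active") {
  list(node_id = node_id, parent_id = parent_id, complex = complex,
       mutations = mutations, scores = NULL, disp = NA_real_,
       improved = NA_integer_, status = status, carried = FALSE)
}

active_ids <- function(dag, layer) {
  ids <- dag$epochs[[layer]]
  ids[vapply(ids, function(i) dag$nodes[[i]]$status == "active", logical(1))]
}

set_restrained <- function(params, restrained) {
  params$restrained <- isTRUE(restrained)
  params
}

# guided-site contributions for one parent: per-residue decomposition of the
# guide scorer on the unperturbed parent pose (frame 1 semantics)
guide_contrib <- function(cx, cfg) {
  if (cfg$chooser$site_mode != "guided") return(NULL)
  nms <- vapply(cfg$scorers, function(s) s$name, character(1))
  guide <- cfg$chooser$guide_scorer
  spec <- if (!is.null(guide)) {
    cfg$scorers[[match(guide, nms)]]
  } else {
    kinds <- vapply(cfg$scorers, function(s) s$kind, character(1))
    i <- which(kinds %in% DECOMPOSABLE_KINDS)[1]
    if (is.na(i)) stop("guided chooser requires a decomposable scorer", call. = FALSE)
    cfg$scorers[[i]]
  }
  per_residue_decomposition(cx, spec)
}

#' Rank survivors and enforce the DAG width
#'
#' Variable mode keeps every survivor.  Constant mode ranks survivors by
#' (number of scorers improved over the parent, descending; then mean
#' across-scorer rank of the average scores, ascending; then node id) and
#' keeps the best `max_width`.
#'
#' @param survivors Named list of `score_table`s (names are node ids).
#' @param mode `"variable"` or `"constant"`.
#' @param max_width Width cap (constant mode).
#' @param improved Optional named integer vector of improved-scorer counts
#'   (defaults to 0 for every survivor).
#' @return Character vector of retained node ids.
#' @export
enforce_width <- function(survivors, mode = c("variable", "constant"),
                          max_width = NULL, improved = NULL) {
  mode <- match.arg(mode)
  ids <- names(survivors)
  if (mode == "variable") return(ids)
  stopifnot(length(survivors) > 0, !is.null(max_width), max_width >= 1)
  if (is.null(improved)) {
    improved <- structure(rep(0L, length(ids)), names = ids)
  }
  scorers <- survivors[[1]]$scorer_names
  avg <- vapply(scorers, function(s) {
    vapply(survivors, function(st) st$averages[[s]], numeric(1))
  }, numeric(length(ids)))
  avg <- matrix(avg, nrow = length(ids),
                dimnames = list(ids, scorers))
  rk <- vapply(seq_along(scorers),
               function(j) rank(avg[, j], ties.method = "average"),
               numeric(length(ids)))
  mean_rank <- rowMeans(matrix(rk, nrow = length(ids)))
  ord <- order(-improved[ids], mean_rank, ids, method = "radix")
  ids[ord[seq_len(min(max_width, length(ids)))]]
}

#' Advance a lineage DAG by one epoch
#'
#' For every active node of the current layer: generate
#' `branches_per_node` distinct mutation sets, apply them, sample an
#' ensemble per mutant (restrained iff the epoch index is within the
#' restrained phase), score it, and prune against the parent.  When no
#' mutant survives (globally in variable mode, per node in constant mode)
#' the parent is carried unchanged into the new layer — the original
#' binders are reused to generate the next set of mutants — with its cached
#' scores.  Constant mode then caps the new layer at `max_width`.  A node
#' whose chooser is exhausted is marked failed; the epoch continues while
#' any node remains.
#'
#' @param dag A lineage DAG as built by [run_optimization()].
#' @param epoch 1-based epoch index being executed.
#' @param cfg The run's `evo_config`.
#' @return The extended DAG; attribute `"all_failed"` is `TRUE` when every
#'   node of the layer failed (the run should stop).
#' @export
run_epoch <- function(dag, epoch, cfg) {
  schedule <- cfg$schedule
  restrained <- epoch <= schedule$restrained_epochs
  parents <- sort(active_ids(dag, length(dag$epochs)))
  if (length(parents) == 0) {
    attr(dag, "all_failed") <- TRUE
    return(dag)
  }
  sampler <- set_restrained(cfg$sampler, restrained)

  # 1. choose mutation sets per parent (chooser exhaustion -> node failed)
  branch_sets <- list()
  for (pid in parents) {
    pnode <- dag$nodes[[pid]]
    msets <- tryCatch({
      contrib <- guide_contrib(pnode$complex, cfg)
      with_substream(derive_seed(cfg$seed, epoch, pid, "choose"),
                     generate_mutations(pnode$complex, cfg$chooser,
                                        schedule$branches_per_node,
                                        contrib = contrib))
    }, error = function(e) e)
    if (inherits(msets, "error")) {
      dag$nodes[[pid]]$status <- "failed"
      dag$nodes[[pid]]$note <- conditionMessage(msets)
    } else {
      branch_sets[[pid]] <- msets
    }
  }
  if (length(branch_sets) == 0) {
    attr(dag, "all_failed") <- TRUE
    return(dag)
  }

  # 2. mutate + sample + score every branch through the worker pool
  tasks <- list()
  for (pid in names(branch_sets)) {
    pnode <- dag$nodes[[pid]]
    for (j in seq_along(branch_sets[[pid]])) {
      payload <- list(cx = pnode$complex, mutations = branch_sets[[pid]][[j]],
                      sampler = sampler, scorers = cfg$scorers)
      tasks[[length(tasks) + 1L]] <- task_spec(
        task_id = sprintf("%s/b%02d", pid, j),
        fun = function(p) {
          mut <- apply_mutation(p$cx, p$mutations)
          ens <- jitter_sample(mut, p$sampler)
          list(complex = mut, scores = score_ensemble(ens, p$scorers),
               disp = ensemble_displacement(ens), ensemble = ens)
        },
        payload = payload,
        seed = derive_seed(cfg$seed, epoch, pid, j, "simulate"))
    }
  }
  results <- run_tasks(tasks, cfg$workers)

  # 3. prune each parent's mutants against it
  next_layer <- character(0)
  counter <- 0L
  retained_any <- FALSE
  per_parent <- list()
  for (pid in names(branch_sets)) {
    pnode <- dag$nodes[[pid]]
    bids <- sprintf("%s/b%02d", pid, seq_along(branch_sets[[pid]]))
    ok <- vapply(bids, function(b) isTRUE(results[[b]]$ok), logical(1))
    tables <- lapply(bids[ok], function(b) results[[b]]$value$scores)
    names(tables) <- bids[ok]
    retained <- if (length(tables) > 0) {
      with_substream(derive_seed(cfg$seed, epoch, pid, "prune"),
                     prune_branches(pnode$scores, tables, cfg$pruner))
    } else character(0)
    improved <- if (length(tables) > 0) {
      count_improved(pnode$scores, tables, tolerance = 0)
    } else integer(0)
    per_parent[[pid]] <- list(bids = bids, ok = ok, retained = retained,
                              improved = improved, sets = branch_sets[[pid]])
    if (length(retained) > 0) retained_any <- TRUE
  }

  # 4. materialize child nodes (deterministic id order: parent, then branch)
  survivors <- list()
  survivor_improved <- integer(0)
  for (pid in names(branch_sets)) {
    pp <- per_parent[[pid]]
    carry_parent <- if (schedule$width_mode == "constant") {
      length(pp$retained) == 0
    } else {
      !retained_any
    }
    for (j in seq_along(pp$bids)) {
      b <- pp$bids[j]
      counter <- counter + 1L
      nid <- sprintf("%d-%d", epoch, counter)
      if (!pp$ok[j]) {
        node <- new_node(nid, pid, NULL, pp$sets[[j]], status = "failed")
        node$note <- results[[b]]$error
      } else {
        st <- if (b %in% pp$retained) "active" else "pruned"
        node <- new_node(nid, pid, results[[b]]$value$complex, pp$sets[[j]],
                        status = st)
        node$scores <- results[[b]]$value$scores
        node$disp <- results[[b]]$value$disp
        node$improved <- unname(pp$improved[[b]])
        if (!is.null(cfg$output_dir)) {
          write_branch_outputs(cfg, epoch, nid, dag$nodes[[pid]]$complex,
                               results[[b]]$value)
        }
        if (st == "active") {
          survivors[[nid]] <- node$scores
          survivor_improved[nid] <- node$improved
        }
      }
      dag$nodes[[nid]] <- node
      next_layer <- c(next_layer, nid)
    }
    if (carry_parent) {
      counter <- counter + 1L
      nid <- sprintf("%d-%d", epoch, counter)
      node <- new_node(nid, pid, dag$nodes[[pid]]$complex, list())
      node$scores <- dag$nodes[[pid]]$scores  # cached, not re-computed
      node$improved <- 0L
      node$carried <- TRUE
      dag$nodes[[nid]] <- node
      next_layer <- c(next_layer, nid)
      survivors[[nid]] <- node$scores
      survivor_improved[nid] <- 0L
    }
  }

  # 5. constant mode caps the new layer's active set
  if (schedule$width_mode == "constant" && length(survivors) > 0) {
    keep <- enforce_width(survivors, "constant", schedule$max_width,
                          improved = survivor_improved)
    for (nid in setdiff(names(survivors), keep)) {
      dag$nodes[[nid]]$status <- "pruned"
    }
  }

  dag$epochs[[length(dag$epochs) + 1L]] <- next_layer
  attr(dag, "all_failed") <- FALSE
  dag
}

#' Run a full optimization
#'
#' Executes the configured number of epochs of the
#' mutate-sample-score-prune cycle starting from the input complex, growing
#' the lineage DAG and (when `output_dir` is set) writing the run directory:
#' per-branch PDBs and score CSVs, a `lineage.json` record and a
#' `trajectory_report.csv` of per-epoch mean scores.  Fully reproducible
#' from (config, seed); stops early when every lineage has failed.
#'
#' @param cfg An `evo_config`.
#' @return An object of class `binder_evolution`; see [evolve_binder()].
#' @export
run_optimization <- function(cfg) {
  stopifnot(inherits(cfg, "evo_config"))
  cx <- resolve_complex(cfg)
  if (nrow(cx$mutable) == 0) stop("no mutable positions declared", call. = FALSE)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  schedule <- cfg$schedule
  root <- new_node("0-0", NULL, cx, list())
  root_sampler <- set_restrained(cfg$sampler, schedule$restrained_epochs >= 1)
  ens <- with_substream(derive_seed(cfg$seed, 0, "0-0", "simulate"),
                        jitter_sample(cx, root_sampler))
  root$scores <- score_ensemble(ens, cfg$scorers)
  root$disp <- ensemble_displacement(ens)
  dag <- list(nodes = list(`0-0` = root), epochs = list("0-0"))
  if (!is.null(cfg$output_dir)) {
    write_branch_outputs(cfg, 0L, "0-0", cx,
                         list(complex = cx, scores = root$scores,
                              disp = root$disp, ensemble = ens))
  }
  stopped_early <- FALSE
  epochs_run <- 0L
  for (epoch in seq_len(schedule$total_epochs)) {
    dag <- run_epoch(dag, epoch, cfg)
    if (isTRUE(attr(dag, "all_failed"))) {
      stopped_early <- TRUE
      break
    }
    epochs_run <- epoch
  }
  obj <- structure(list(dag = dag, config = cfg, seed = cfg$seed,
                        epochs_run = epochs_run,
                        stopped_early = stopped_early,
                        trajectory = trajectory_report(dag, cfg)),
                   class = "binder_evolution")
  if (!is.null(cfg$output_dir)) {
    write_lineage_json(obj, file.path(cfg$output_dir, "lineage.json"))
    utils::write.csv(obj$trajectory,
                     file.path(cfg$output_dir, "trajectory_report.csv"),
                     row.names = FALSE)
  }
  obj
}

#' Optimize a binder toward its target
#'
#' The main entry point of the package: assembles a run configuration from
#' its pieces (or takes a ready-made one) and runs the evolutionary
#' optimization.
#'
#' @param complex A `complex_model`, or a PDB path (character).
#' @param ... Passed to [evo_config()] (chooser, sampler, scorers, pruner,
#'   schedule, seed, workers, output_dir, ...).
#' @param config A complete `evo_config`; when supplied, `complex` and
#'   `...` are ignored.
#' @return A `binder_evolution` object with `print`, `summary`, `plot` and
#'   `as.data.frame` methods.
#' @export
evolve_binder <- function(complex = NULL, ..., config = NULL) {
  if (is.null(config)) {
    config <- if (is.character(complex)) {
      evo_config(input_pdb = complex, ...)
    } else {
      evo_config(complex = complex, ...)
    }
  }
  run_optimization(config)
}

# per-epoch mean of each scorer's average over the layer's active nodes
trajectory_report <- function(dag, cfg) {
  nms <- vapply(cfg$scorers, function(s) s$name, character(1))
  rows <- list()
  for (e in seq_along(dag$epochs)) {
    ids <- dag$epochs[[e]]
    act <- ids[vapply(ids, function(i) dag$nodes[[i]]$status == "active", logical(1))]
    if (length(act) == 0) act <- ids[vapply(ids, function(i) !is.null(dag$nodes[[i]]$scores), logical(1))]
    epoch <- e - 1L
    phase <- if (epoch == 0L) {
      if (cfg$schedule$restrained_epochs >= 1L) "restrained" else "unrestrained"
    } else if (epoch <= cfg$schedule$restrained_epochs) "restrained" else "unrestrained"
    for (s in nms) {
      vals <- vapply(act, function(i) dag$nodes[[i]]$scores$averages[[s]], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = epoch, phase = phase, scorer = s,
        mean_score = mean(vals), n_active = length(act),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

write_branch_outputs <- function(cfg, epoch, nid, parent_cx, result) {
  bdir <- file.path(cfg$output_dir, sprintf("epoch_%02d", epoch),
                    gsub("/", "_", nid))
  dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(parent_cx, file.path(bdir, "input.pdb"))
  write_pdb(result$complex, file.path(bdir, "mutated.pdb"))
  write_pdb(result$complex, file.path(bdir, "ensemble.pdb"),
            ensemble = result$ensemble)
  st <- result$scores
  rows <- do.call(rbind, lapply(st$scorer_names, function(s) {
    data.frame(epoch = epoch, branch = nid, scorer = s,
               frame = seq_along(st$per_frame[[s]]),
               score = st$per_frame[[s]], average = st$averages[[s]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file.path(bdir, "scores.csv"), row.names = FALSE)
}

write_lineage_json <- function(obj, path) {
  dag <- obj$dag
  nodes <- lapply(dag$nodes, function(n) {
    list(node_id = n$node_id,
         parent_id = if (is.null(n$parent_id)) NA else n$parent_id,
         mutations = vapply(n$mutations, format_mutation, character(1)),
         status = n$status,
         carried = n$carried,
         averages = if (is.null(n$scores)) NULL else as.list(n$scores$averages),
         mean_centroid_displacement = n$disp,
         improved_scorers = n$improved)
  })
  jsonlite::write_json(list(seed = obj$seed,
                            epochs = dag$epochs,
                            stopped_early = obj$stopped_early,
                            nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Replay a node's mutation chain from the root
#'
#' Walks the parent chain of `node_id` and re-applies every recorded
#' mutation set to the root complex; the reconstructed binder sequence must
#' equal the stored node's — the lineage-consistency invariant of the DAG.
#'
#' @param obj A `binder_evolution`.
#' @param node_id Node to replay.
#' @return Named character vector: the replayed binder sequence.
#' @export
replay_lineage <- function(obj, node_id) {
  dag <- obj$dag
  chain <- list()
  cur <- node_id
  while (!is.null(cur)) {
    chain[[length(chain) + 1L]] <- dag$nodes[[cur]]
    cur <- dag$nodes[[cur]]$parent_id
  }
  cx <- chain[[length(chain)]]$complex  # root
  for (k in rev(seq_len(length(chain) - 1L))) {
    cx <- apply_mutation(cx, chain[[k]]$mutations)
  }
  binder_sequence(cx)
}
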