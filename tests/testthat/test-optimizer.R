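quiet_sampler <- function(n = 2) {
  sampler_params(n_frames = n, rigid_rot_max = 0, rigid_trans_max = 0,
                 residue_noise_sd = 0)
}

base_cfg <- function(cx, ..., scorers = list(scorer("cc", "contact_count")),
                     sampler = quiet_sampler()) {
  evo_config(complex = cx, scorers = scorers, sampler = sampler, ...)
}

test_that("a zero-epoch run scores the root and nothing else", {
  cx <- make_toy_complex(8, 8, "two_strands", interface_gap = 5, seed = 1)
  res <- run_optimization(base_cfg(cx, schedule = epoch_schedule(0), seed = 1))
  expect_length(res$dag$nodes, 1)
  expect_identical(names(res$dag$nodes), "0-0")
  expect_false(is.null(res$dag$nodes[["0-0"]]$scores))
  expect_equal(res$epochs_run, 0L)
})

test_that("variable-width growth: all-retaining pruning multiplies the active set", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 2)
  res <- run_optimization(base_cfg(cx,
    pruner = pruner_spec("consensus_threshold", consensus_k = 0),
    schedule = epoch_schedule(3, branches_per_node = 3, width_mode = "variable"),
    seed = 3))
  widths <- vapply(seq_along(res$dag$epochs), function(e) {
    length(evobinder:::active_ids(res$dag, e))
  }, integer(1))
  expect_equal(widths, c(1L, 3L, 9L, 27L))
})

test_that("constant mode caps the active width after every epoch", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 4)
  res <- run_optimization(base_cfg(cx,
    pruner = pruner_spec("consensus_threshold", consensus_k = 0),
    schedule = epoch_schedule(6, branches_per_node = 4, width_mode = "constant",
                              max_width = 2),
    seed = 5))
  for (e in 2:length(res$dag$epochs)) {
    expect_lte(length(evobinder:::active_ids(res$dag, e)), 2)
  }
  expect_equal(res$epochs_run, 6L)
})

test_that("chooser exhaustion marks nodes failed and stops the run gracefully", {
  cx <- make_toy_complex(6, 6, "two_strands", interface_gap = 5, seed = 6)
  cx$mutable <- cx$mutable[1, , drop = FALSE]
  cur <- binder_sequence(cx)[[1]]
  grp <- c(cur, setdiff(AA20, cur)[1:2])  # only 2 distinct substitutions
  res <- run_optimization(base_cfg(cx,
    chooser = chooser_policy(aa_scheme = "grouped", groups = list(g = grp),
                             active_group = "g"),
    pruner = pruner_spec("consensus_threshold", consensus_k = 0),
    schedule = epoch_schedule(5, branches_per_node = 4),
    seed = 7))
  expect_true(res$stopped_early)
  expect_equal(res$epochs_run, 0L)
  expect_identical(res$dag$nodes[["0-0"]]$status, "failed")
  expect_match(res$dag$nodes[["0-0"]]$note, "at most")
})

test_that("with a never-retaining pruner the original binder is reused every epoch", {
  cx <- make_toy_complex(8, 8, "two_strands", interface_gap = 5, seed = 8)
  root_seq <- binder_sequence(cx)
  res <- run_optimization(base_cfg(cx,
    pruner = pruner_spec("consensus_threshold", consensus_k = 1, tolerance = 1e9),
    schedule = epoch_schedule(6, branches_per_node = 3),
    seed = 9))
  expect_false(res$stopped_early)
  expect_equal(res$epochs_run, 6L)
  for (e in 2:length(res$dag$epochs)) {
    act <- evobinder:::active_ids(res$dag, e)
    expect_length(act, 1)
    node <- res$dag$nodes[[act]]
    expect_true(node$carried)
    expect_length(node$mutations, 0)
    expect_identical(binder_sequence(node$complex), root_seq)
    # cached parent scores, never re-computed
    expect_identical(node$scores, res$dag$nodes[["0-0"]]$scores)
  }
})

test_that("the DAG stays layered and acyclic with consistent parents", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 10)
  res <- run_optimization(base_cfg(cx,
    sampler = sampler_params(n_frames = 3),
    pruner = pruner_spec("metropolis", temperature = 1),
    schedule = epoch_schedule(4, branches_per_node = 3, width_mode = "constant",
                              max_width = 3),
    seed = 11))
  for (e in seq_along(res$dag$epochs)) {
    for (id in res$dag$epochs[[e]]) {
      node <- res$dag$nodes[[id]]
      if (e == 1) {
        expect_null(node$parent_id)
        expect_length(node$mutations, 0)
      } else {
        expect_true(node$parent_id %in% res$dag$epochs[[e - 1]])
        # a parent must have been active in the previous layer
        expect_identical(res$dag$nodes[[node$parent_id]]$status, "active")
      }
      if (!is.null(node$scores) && node$status != "failed") {
        expect_true(all(is.finite(node$scores$averages)))
      }
    }
  }
})

test_that("lineage replay reconstructs every node's sequence from the root", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 12)
  res <- run_optimization(base_cfg(cx,
    pruner = pruner_spec("consensus_threshold", consensus_k = 0),
    schedule = epoch_schedule(4, branches_per_node = 2, width_mode = "constant",
                              max_width = 2),
    seed = 13))
  for (id in names(res$dag$nodes)) {
    node <- res$dag$nodes[[id]]
    if (node$status == "failed") next
    expect_identical(replay_lineage(res, id), binder_sequence(node$complex))
  }
})

test_that("greedy top-1 pruning never lets the retained score increase", {
  cx <- make_toy_complex(12, 12, "two_strands", interface_gap = 5, seed = 14)
  opt <- binder_sequence(cx)
  start <- plant_suboptimal(cx, opt, 4, seed = 15)
  res <- run_optimization(base_cfg(start,
    scorers = list(hidden_oracle_scorer(opt)),
    pruner = pruner_spec("top_n", keep_n = 1, reference_scorer = "oracle"),
    schedule = epoch_schedule(15, branches_per_node = 5, width_mode = "constant",
                              max_width = 1),
    seed = 16))
  best <- vapply(seq_along(res$dag$epochs), function(e) {
    act <- evobinder:::active_ids(res$dag, e)
    min(vapply(act, function(i) res$dag$nodes[[i]]$scores$averages[["oracle"]],
               numeric(1)))
  }, numeric(1))
  expect_true(all(diff(best) <= 1e-12))
})

test_that("identical config and seed give bit-identical lineage records", {
  cx <- make_toy_complex(8, 8, "two_strands", interface_gap = 5, seed = 17)
  run_once <- function(dir) {
    run_optimization(base_cfg(cx,
      sampler = sampler_params(n_frames = 3),
      pruner = pruner_spec("consensus_threshold", consensus_k = 1),
      schedule = epoch_schedule(3, branches_per_node = 2),
      seed = 18, output_dir = dir))
  }
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_once(d1); r2 <- run_once(d2)
  expect_identical(readLines(file.path(d1, "lineage.json")),
                   readLines(file.path(d2, "lineage.json")))
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("enforce_width ranks by improvement count, mean rank, then id", {
  mk <- function(a, b) evobinder:::new_score_table(list(s1 = rep(a, 2), s2 = rep(b, 2)))
  survivors <- list(n1 = mk(-1, -1), n2 = mk(-5, -5), n3 = mk(-3, -6), n4 = mk(-6, -3))
  expect_setequal(enforce_width(survivors, "variable"), names(survivors))
  # improvement counts dominate
  imp <- c(n1 = 2L, n2 = 0L, n3 = 1L, n4 = 1L)
  keep <- enforce_width(survivors, "constant", 2, improved = imp)
  expect_identical(keep[1], "n1")
  expect_true(keep[2] %in% c("n3", "n4"))
  # with equal improvement, mean across-scorer rank decides; n3/n4 tie on
  # mean rank and break by id; full-sort oracle agreement on random tables
  set.seed(19)
  for (trial in 1:10) {
    sv <- setNames(lapply(1:6, function(i) mk(rnorm(1), rnorm(1))),
                   sprintf("m%d", 1:6))
    keep <- enforce_width(sv, "constant", 2)
    a1 <- vapply(sv, function(t) t$averages[["s1"]], numeric(1))
    a2 <- vapply(sv, function(t) t$averages[["s2"]], numeric(1))
    mr <- (rank(a1) + rank(a2)) / 2
    oracle <- names(sort(mr))[1:2]
    expect_setequal(keep, oracle)
  }
})

test_that("two-phase schedules mark the boundary and relax after the restraints lift", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 20)
  res <- run_optimization(base_cfg(cx,
    sampler = sampler_params(n_frames = 4),
    pruner = pruner_spec("consensus_threshold", consensus_k = 1),
    schedule = epoch_schedule(6, restrained_epochs = 3, branches_per_node = 2,
                              width_mode = "constant", max_width = 2),
    seed = 21))
  tr <- res$trajectory
  expect_setequal(unique(tr$phase[tr$epoch >= 1 & tr$epoch <= 3]), "restrained")
  expect_setequal(unique(tr$phase[tr$epoch > 3]), "unrestrained")
  disp <- vapply(res$dag$nodes, function(n) n$disp, numeric(1))
  ep <- as.integer(sub("-.*", "", names(disp)))
  d_restr <- disp[ep >= 1 & ep <= 3]
  d_free <- disp[ep > 3]
  expect_lt(mean(d_restr, na.rm = TRUE), mean(d_free, na.rm = TRUE))
})
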