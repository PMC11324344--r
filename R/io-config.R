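# Run configuration: a YAML dialect mirroring the engine's blocks
# (chooser / sampler / scorers / pruner / schedule), validated as a whole so
# the user sees every problem at once.

#' Epoch schedule
#'
#' The shape of an optimization run: how many epochs, how many of the first
#' epochs sample under positional restraints (the restrained phase of a
#' two-phase protocol), how many branches each active node spawns, and how
#' DAG width is managed — `"variable"` (all survivors continue) or
#' `"constant"` (survivors are ranked and capped at `max_width`).
#'
#' @param total_epochs Number of epochs (>= 0).
#' @param restrained_epochs Leading epochs sampled in restrained mode
#'   (0 <= restrained_epochs <= total_epochs).
#' @param branches_per_node Mutant branches generated per active node
#'   (default 4).
#' @param width_mode `"variable"` or `"constant"`.
#' @param max_width Active-node cap in constant mode (default 4).
#' @return An object of class `epoch_schedule`.
#' @export
epoch_schedule <- function(total_epochs, restrained_epochs = 0L,
                           branches_per_node = 4L,
                           width_mode = c("variable", "constant"),
                           max_width = 4L) {
  width_mode <- match.arg(width_mode)
  total_epochs <- as.integer(total_epochs)
  restrained_epochs <- as.integer(restrained_epochs)
  branches_per_node <- as.integer(branches_per_node)
  max_width <- as.integer(max_width)
  stopifnot(total_epochs >= 0L, restrained_epochs >= 0L, branches_per_node >= 1L,
            max_width >= 1L)
  if (restrained_epochs > total_epochs) {
    stop("restrained_epochs cannot exceed total_epochs", call. = FALSE)
  }
  structure(list(total_epochs = total_epochs,
                 restrained_epochs = restrained_epochs,
                 branches_per_node = branches_per_node,
                 width_mode = width_mode, max_width = max_width),
            class = "epoch_schedule")
}

#' Assemble a run configuration
#'
#' Collects every block of an optimization run into one validated object.
#' Either `complex` (an in-memory model) or `input_pdb` plus the chain
#' partition must be supplied.
#'
#' @param complex A `complex_model`, or `NULL` to read `input_pdb`.
#' @param input_pdb Path to the starting complex (used when `complex` is
#'   `NULL`).
#' @param binder_chains,target_chains Chain partition for `input_pdb`.
#' @param mutable_positions Character vector of `chain:start-end` intervals
#'   (1-based, inclusive), e.g. `"A:2-11"`; `NULL` means every binder
#'   residue.
#' @param chooser A [chooser_policy()].
#' @param sampler A [sampler_params()].
#' @param scorers List of [scorer()] specifications (>= 1, unique names).
#' @param pruner A [pruner_spec()].
#' @param schedule An [epoch_schedule()].
#' @param seed Master seed (integer).
#' @param workers Worker-pool size for sampling/scoring tasks (default 1).
#' @param output_dir Run directory for PDB/CSV/lineage output, or `NULL`
#'   for an in-memory run.
#' @return An object of class `evo_config`.
#' @export
evo_config <- function(complex = NULL, input_pdb = NULL, binder_chains = NULL,
                       target_chains = NULL, mutable_positions = NULL,
                       chooser = chooser_policy(), sampler = sampler_params(),
                       scorers = list(scorer("contacts", "contact_count")),
                       pruner = pruner_spec(), schedule = epoch_schedule(5),
                       seed = 1L, workers = 1L, output_dir = NULL) {
  cfg <- structure(list(complex = complex, input_pdb = input_pdb,
                        binder_chains = binder_chains,
                        target_chains = target_chains,
                        mutable_positions = mutable_positions,
                        chooser = chooser, sampler = sampler, scorers = scorers,
                        pruner = pruner, schedule = schedule,
                        seed = as.integer(seed), workers = as.integer(workers),
                        output_dir = output_dir),
                   class = "evo_config")
  probs <- validate_config(cfg)
  if (length(probs) > 0) {
    stop(paste(c("invalid run configuration:", paste(" -", probs)),
               collapse = "\n"), call. = FALSE)
  }
  cfg
}

#' Validate a run configuration
#'
#' Checks every cross-reference (scorer names, pruner consensus threshold,
#' chain partition, mutable intervals) and returns the complete list of
#' problems instead of stopping at the first.
#'
#' @param cfg An `evo_config` (possibly under construction).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  probs <- character(0)
  if (is.null(cfg$complex) && is.null(cfg$input_pdb)) {
    probs <- c(probs, "either complex or input_pdb must be supplied")
  }
  if (!is.null(cfg$input_pdb) && is.null(cfg$complex) && !file.exists(cfg$input_pdb)) {
    probs <- c(probs, sprintf("input_pdb not found: %s", cfg$input_pdb))
  }
  if (!inherits(cfg$chooser, "chooser_policy")) probs <- c(probs, "chooser is not a chooser_policy")
  if (!inherits(cfg$sampler, "sampler_params")) probs <- c(probs, "sampler is not sampler_params")
  if (!inherits(cfg$pruner, "pruner_spec")) probs <- c(probs, "pruner is not a pruner_spec")
  if (!inherits(cfg$schedule, "epoch_schedule")) probs <- c(probs, "schedule is not an epoch_schedule")
  if (length(cfg$scorers) == 0) {
    probs <- c(probs, "at least one scorer is required")
  } else {
    ok <- vapply(cfg$scorers, inherits, logical(1), what = "scorer_spec")
    if (!all(ok)) probs <- c(probs, "scorers must all be scorer() specifications")
    nms <- vapply(cfg$scorers[ok], function(s) s$name, character(1))
    if (anyDuplicated(nms)) probs <- c(probs, "scorer names must be unique")
    if (inherits(cfg$pruner, "pruner_spec")) {
      if (cfg$pruner$kind == "consensus_threshold" &&
          cfg$pruner$consensus_k > length(cfg$scorers)) {
        probs <- c(probs, sprintf("consensus_k (%d) exceeds the number of scorers (%d)",
                                  cfg$pruner$consensus_k, length(cfg$scorers)))
      }
      ref <- cfg$pruner$reference_scorer
      if (!is.null(ref) && !(ref %in% nms)) {
        probs <- c(probs, sprintf("reference_scorer '%s' is not a configured scorer", ref))
      }
    }
    if (inherits(cfg$chooser, "chooser_policy") && !is.null(cfg$chooser$guide_scorer) &&
        !(cfg$chooser$guide_scorer %in% nms)) {
      probs <- c(probs, sprintf("guide_scorer '%s' is not a configured scorer",
                                cfg$chooser$guide_scorer))
    }
  }
  if (!is.null(cfg$complex) && !inherits(cfg$complex, "complex_model")) {
    probs <- c(probs, "complex is not a complex_model")
  }
  probs
}

# expand "A:2-11" interval strings against a residue table
parse_mutable_intervals <- function(strings, residues) {
  out <- list()
  for (s in strings) {
    mm <- regmatches(s, regexec("^(.):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(mm) != 4) {
      mm1 <- regmatches(s, regexec("^(.):([0-9]+)$", s))[[1]]
      if (length(mm1) != 3) {
        stop(sprintf("malformed mutable interval '%s' (expected 'A:2-11' or 'A:7')", s),
             call. = FALSE)
      }
      mm <- c(mm1, mm1[3])
    }
    ch <- mm[2]; lo <- as.integer(mm[3]); hi <- as.integer(mm[4])
    if (hi < lo) stop(sprintf("empty mutable interval '%s'", s), call. = FALSE)
    sel <- residues$chain == ch & residues$pos >= lo & residues$pos <= hi
    out[[length(out) + 1L]] <- data.frame(chain = residues$chain[sel],
                                          pos = residues$pos[sel],
                                          stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, out))
}

# materialize cfg$complex (reading input_pdb if needed)
resolve_complex <- function(cfg) {
  if (!is.null(cfg$complex)) return(cfg$complex)
  cx <- read_pdb(cfg$input_pdb, binder_chains = cfg$binder_chains,
                 target_chains = cfg$target_chains)
  if (!is.null(cfg$mutable_positions)) {
    cx$mutable <- parse_mutable_intervals(cfg$mutable_positions, cx$residues)
    validate_complex(cx)
  }
  cx
}

scorer_to_list <- function(s) {
  out <- list(name = s$name, kind = s$kind, sign = s$sign, cutoff = s$cutoff,
              screen_len = s$screen_len, weight = s$weight)
  if (!is.null(s$optimal_seq)) out$optimal_seq <- as.list(s$optimal_seq)
  out
}

scorer_from_list <- function(x) {
  args <- list(name = x$name, kind = x$kind)
  for (f in c("sign", "cutoff", "screen_len", "weight")) {
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  }
  if (!is.null(x$optimal_seq)) {
    args$optimal_seq <- unlist(x$optimal_seq)
  }
  if (!is.null(x$matrix_file)) args$matrix <- read_contact_matrix(x$matrix_file)
  if (is.null(args$kind) || !args$kind %in% SCORER_KINDS) {
    stop(sprintf("unknown scorer kind '%s' for scorer '%s'",
                 if (is.null(args$kind)) "<missing>" else args$kind,
                 if (is.null(args$name)) "<unnamed>" else args$name), call. = FALSE)
  }
  do.call(scorer, args)
}

#' Load a run configuration from YAML
#'
#' Reads the documented YAML dialect, fills defaults for every omitted
#' field, and validates the whole configuration, reporting every problem at
#' once.
#'
#' @param path YAML file path.
#' @return An `evo_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  probs <- character(0)
  ch <- y$chooser
  chooser <- tryCatch(do.call(chooser_policy, c(
    list(site_mode = ch$site_mode %||% "random",
         aa_scheme = ch$aa_scheme %||% "uniform",
         sites_per_mutant = ch$sites_per_mutant %||% 1L),
    if (!is.null(ch$aa_probs)) list(aa_probs = unlist(ch$aa_probs)),
    if (!is.null(ch$groups)) list(groups = lapply(ch$groups, unlist)),
    if (!is.null(ch$active_group)) list(active_group = ch$active_group),
    if (!is.null(ch$guide_scorer)) list(guide_scorer = ch$guide_scorer))),
    error = function(e) { probs <<- c(probs, conditionMessage(e)); chooser_policy() })
  sp <- y$sampler
  sampler <- tryCatch(sampler_params(
    n_frames = sp$n_frames %||% 10L,
    rigid_rot_max = sp$rigid_rot_max %||% 5,
    rigid_trans_max = sp$rigid_trans_max %||% 1,
    residue_noise_sd = sp$residue_noise_sd %||% 0.3,
    restraint_factor = sp$restraint_factor %||% 0.2),
    error = function(e) { probs <<- c(probs, conditionMessage(e)); sampler_params() })
  scorers <- if (is.null(y$scorers)) {
    list(scorer("contacts", "contact_count"))
  } else {
    lapply(y$scorers, function(x) {
      tryCatch(scorer_from_list(x),
               error = function(e) { probs <<- c(probs, conditionMessage(e)); NULL })
    })
  }
  scorers <- Filter(Negate(is.null), scorers)
  pr <- y$pruner
  pruner <- tryCatch(pruner_spec(
    kind = pr$kind %||% "consensus_threshold",
    consensus_k = pr$consensus_k %||% 1L,
    tolerance = pr$tolerance %||% 0,
    temperature = pr$temperature %||% 1,
    keep_n = pr$keep_n %||% 1L,
    reference_scorer = pr$reference_scorer),
    error = function(e) { probs <<- c(probs, conditionMessage(e)); pruner_spec() })
  sc <- y$schedule
  schedule <- tryCatch(epoch_schedule(
    total_epochs = sc$total_epochs %||% 5L,
    restrained_epochs = sc$restrained_epochs %||% 0L,
    branches_per_node = sc$branches_per_node %||% 4L,
    width_mode = sc$width_mode %||% "variable",
    max_width = sc$max_width %||% 4L),
    error = function(e) { probs <<- c(probs, conditionMessage(e)); epoch_schedule(5) })
  cfg <- structure(list(complex = NULL, input_pdb = y$input_pdb,
                        binder_chains = y$binder_chains,
                        target_chains = y$target_chains,
                        mutable_positions = y$mutable_positions,
                        chooser = chooser, sampler = sampler, scorers = scorers,
                        pruner = pruner, schedule = schedule,
                        seed = as.integer(y$seed %||% 1L),
                        workers = as.integer(y$workers %||% 1L),
                        output_dir = y$output_dir),
                   class = "evo_config")
  probs <- c(probs, validate_config(cfg))
  if (length(probs) > 0) {
    stop(paste(c(sprintf("invalid run configuration (%s):", path),
                 paste(" -", probs)), collapse = "\n"), call. = FALSE)
  }
  cfg
}

#' Write a run configuration as YAML
#'
#' Inverse of [load_config()]: the dumped file loads back to an equivalent
#' configuration (load -> dump -> load is idempotent).  The in-memory
#' `complex`, if any, is not serialized; point `input_pdb` at a structure
#' file instead.
#'
#' @param cfg An `evo_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "evo_config"))
  ch <- cfg$chooser
  y <- list(
    input_pdb = cfg$input_pdb,
    binder_chains = cfg$binder_chains,
    target_chains = cfg$target_chains,
    mutable_positions = cfg$mutable_positions,
    chooser = Filter(Negate(is.null), list(
      site_mode = ch$site_mode, aa_scheme = ch$aa_scheme,
      sites_per_mutant = ch$sites_per_mutant,
      aa_probs = if (!is.null(ch$aa_probs)) as.list(ch$aa_probs),
      groups = if (ch$aa_scheme == "grouped") lapply(ch$groups, as.list),
      active_group = ch$active_group,
      guide_scorer = ch$guide_scorer)),
    sampler = cfg$sampler[c("n_frames", "rigid_rot_max", "rigid_trans_max",
                            "residue_noise_sd", "restraint_factor")],
    scorers = lapply(cfg$scorers, scorer_to_list),
    pruner = Filter(Negate(is.null),
                    cfg$pruner[c("kind", "consensus_k", "tolerance", "temperature",
                                 "keep_n", "reference_scorer")]),
    schedule = cfg$schedule[c("total_epochs", "restrained_epochs",
                              "branches_per_node", "width_mode", "max_width")],
    seed = cfg$seed, workers = cfg$workers, output_dir = cfg$output_dir)
  yaml::write_yaml(Filter(Negate(is.null), y), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
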