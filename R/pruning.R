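#' Pruner specification
#'
#' Configures how mutant lineages are retained or stopped at the end of an
#' epoch.  Three built-in kinds:
#' \describe{
#'   \item{`consensus_threshold`}{a mutant survives iff at least
#'     `consensus_k` scorers judge it improved over its parent by more than
#'     `tolerance`.}
#'   \item{`metropolis`}{Monte Carlo acceptance on a single reference
#'     scorer: always accept an improvement, accept a worsening of
#'     `delta` with probability `exp(-delta / temperature)` — giving a
#'     chance to mutations predicted to slightly lower affinity.}
#'   \item{`top_n`}{keep the `keep_n` mutants with the lowest average on
#'     the reference scorer, ties broken by branch id.}
#' }
#'
#' @param kind One of `"consensus_threshold"`, `"metropolis"`, `"top_n"`.
#' @param consensus_k Minimum number of improving scorers (consensus).
#' @param tolerance Improvement margin, score units (>= 0, default 0).
#' @param temperature Metropolis temperature, score units (> 0, default 1).
#' @param keep_n Survivors per pruning pool (top_n, default 1).
#' @param reference_scorer Scorer name used by metropolis/top_n; defaults
#'   to the first configured scorer.
#' @return An object of class `pruner_spec`.
#' @export
pruner_spec <- function(kind = c("consensus_threshold", "metropolis", "top_n"),
                        consensus_k = 1L, tolerance = 0, temperature = 1,
                        keep_n = 1L, reference_scorer = NULL) {
  kind <- match.arg(kind)
  consensus_k <- as.integer(consensus_k)
  keep_n <- as.integer(keep_n)
  stopifnot(tolerance >= 0)
  if (kind == "metropolis" && temperature <= 0) {
    stop("metropolis temperature must be > 0", call. = FALSE)
  }
  if (kind == "top_n" && keep_n < 1L) {
    stop("keep_n must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, consensus_k = consensus_k, tolerance = tolerance,
                 temperature = temperature, keep_n = keep_n,
                 reference_scorer = reference_scorer),
            class = "pruner_spec")
}

check_same_scorers <- function(parent, mutants) {
  for (st in mutants) {
    if (!identical(sort(st$scorer_names), sort(parent$scorer_names))) {
      stop("score tables do not share scorer names", call. = FALSE)
    }
  }
}

#' Count scorers improved over the parent
#'
#' For each mutant, the number of scorers whose average is strictly below
#' the parent's average minus `tolerance` — the quantity the consensus
#' criterion thresholds, and the primary ranking key of constant-width DAG
#' management.
#'
#' @param parent `score_table` of the parent complex.
#' @param mutants Named list of mutant `score_table`s.
#' @param tolerance Improvement margin (>= 0).
#' @return Named integer vector, one count per mutant.
#' @export
count_improved <- function(parent, mutants, tolerance = 0) {
  check_same_scorers(parent, mutants)
  vapply(mutants, function(st) {
    sum(st$averages[parent$scorer_names] < parent$averages - tolerance)
  }, integer(1))
}

#' Consensus-threshold pruning
#'
#' Retains a mutant branch iff at least `consensus_k` scorers judge it
#' improved over the parent by more than `tolerance`.
#'
#' @param parent `score_table` of the parent.
#' @param mutants Named list of mutant `score_table`s (names are branch
#'   ids).
#' @param spec A [pruner_spec()] of kind `consensus_threshold`.
#' @return Character vector of retained branch ids, with the per-branch
#'   improvement counts attached as attribute `"improved"`.
#' @export
consensus_prune <- function(parent, mutants, spec) {
  if (spec$consensus_k > length(parent$scorer_names)) {
    warning("consensus_k exceeds the number of scorers; nothing can be retained")
  }
  imp <- count_improved(parent, mutants, spec$tolerance)
  structure(names(imp)[imp >= spec$consensus_k], improved = imp)
}

#' Metropolis Monte Carlo acceptance
#'
#' Accepts a mutant with probability `min(1, exp(-(mutant - parent) /
#' temperature))`: improvements always pass, worsenings pass with
#' Boltzmann probability.  Uses the session RNG; seed for reproducibility.
#'
#' @param parent_avg,mutant_avg Average scores being compared (finite).
#' @param spec A [pruner_spec()] of kind `metropolis`.
#' @return Logical: accept the mutant?
#' @export
metropolis_prune <- function(parent_avg, mutant_avg, spec) {
  if (!is.finite(parent_avg) || !is.finite(mutant_avg)) {
    stop("metropolis pruning requires finite scores", call. = FALSE)
  }
  delta <- mutant_avg - parent_avg
  if (delta <= 0) return(TRUE)
  runif(1) < exp(-delta / spec$temperature)
}

#' Top-N pruning
#'
#' Keeps the `keep_n` mutants with the lowest average on the reference
#' scorer; ties are broken by branch id in lexicographic order.
#'
#' @param mutants Named list of mutant `score_table`s.
#' @param spec A [pruner_spec()] of kind `top_n`; `reference_scorer`
#'   defaults to the first scorer of the tables.
#' @return Character vector of retained branch ids.
#' @export
top_prune <- function(mutants, spec) {
  if (length(mutants) == 0) return(character(0))
  ref <- spec$reference_scorer
  if (is.null(ref)) ref <- mutants[[1]]$scorer_names[1]
  vals <- vapply(mutants, function(st) {
    if (!ref %in% st$scorer_names) {
      stop(sprintf("reference scorer '%s' missing from a score table", ref),
           call. = FALSE)
    }
    st$averages[[ref]]
  }, numeric(1))
  ids <- names(vals)
  ord <- order(vals, ids, method = "radix")
  ids[ord[seq_len(min(spec$keep_n, length(ids)))]]
}

# dispatch a pruning decision for one parent's mutants; metropolis draws one
# uniform per mutant in branch-id order (deterministic under a substream).
prune_branches <- function(parent, mutants, spec) {
  switch(spec$kind,
    consensus_threshold = as.character(consensus_prune(parent, mutants, spec)),
    metropolis = {
      ref <- spec$reference_scorer
      if (is.null(ref)) ref <- parent$scorer_names[1]
      ids <- sort(names(mutants))
      keep <- vapply(ids, function(id) {
        metropolis_prune(parent$averages[[ref]], mutants[[id]]$averages[[ref]], spec)
      }, logical(1))
      ids[keep]
    },
    top_n = {
      # the parent competes for the keep_n slots: a mutant is retained only
      # if it outranks the parent into the top keep_n, so the retained
      # lineage never gets worse under greedy settings
      ref <- spec$reference_scorer
      if (is.null(ref)) ref <- parent$scorer_names[1]
      pool <- c(mutants, list(`..parent..` = parent))
      top <- top_prune(pool, spec)
      setdiff(top, "..parent..")
    })
}
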