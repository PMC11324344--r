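#' Mutation chooser policy
#'
#' Configures how the engine picks mutation sites and replacement residues.
#' Site selection is either `"random"` (uniform over the declared mutable
#' positions) or `"guided"` (the residues contributing least favourably to
#' the interface score, as judged by a per-residue decomposition of a
#' scorer).  The replacement scheme is `"uniform"` over the 19 alternative
#' residues, `"custom"` with user weights, or `"grouped"` within one
#' physico-chemical category.
#'
#' @param site_mode `"random"` or `"guided"`.
#' @param aa_scheme `"uniform"`, `"custom"` or `"grouped"`.
#' @param aa_probs Named non-negative weights over one-letter codes
#'   (custom scheme); renormalized internally, so only ratios matter.
#' @param groups Named list of one-letter code sets (grouped scheme);
#'   defaults to [default_aa_groups()].
#' @param active_group Name of the group to draw replacements from
#'   (grouped scheme).
#' @param sites_per_mutant Number of distinct sites mutated together in one
#'   branch (default 1).
#' @param guide_scorer Optional scorer name whose per-residue decomposition
#'   drives guided site selection during an optimization run; defaults to the
#'   first decomposable scorer in the run configuration.
#' @return An object of class `chooser_policy`.
#' @export
chooser_policy <- function(site_mode = c("random", "guided"),
                           aa_scheme = c("uniform", "custom", "grouped"),
                           aa_probs = NULL, groups = default_aa_groups(),
                           active_group = NULL, sites_per_mutant = 1L,
                           guide_scorer = NULL) {
  site_mode <- match.arg(site_mode)
  aa_scheme <- match.arg(aa_scheme)
  sites_per_mutant <- as.integer(sites_per_mutant)
  stopifnot(sites_per_mutant >= 1L)
  if (aa_scheme == "custom") {
    if (is.null(aa_probs) || is.null(names(aa_probs))) {
      stop("custom scheme requires named aa_probs", call. = FALSE)
    }
    check_aa(names(aa_probs))
    if (any(aa_probs < 0) || sum(aa_probs) <= 0) {
      stop("aa_probs must be non-negative with a positive sum", call. = FALSE)
    }
  }
  if (aa_scheme == "grouped") {
    if (is.null(active_group) || is.null(groups[[active_group]]) ||
        length(groups[[active_group]]) == 0) {
      stop("grouped scheme requires a non-empty active_group present in groups",
           call. = FALSE)
    }
    check_aa(unlist(groups))
  }
  structure(list(site_mode = site_mode, aa_scheme = aa_scheme,
                 aa_probs = aa_probs, groups = groups,
                 active_group = active_group,
                 sites_per_mutant = sites_per_mutant,
                 guide_scorer = guide_scorer),
            class = "chooser_policy")
}

# uniform sample of one element (avoids sample()'s scalar surprise)
sample_one <- function(x) x[[sample.int(length(x), 1L)]]

#' Choose a mutation site
#'
#' Random mode draws uniformly over the mutable positions.  Guided mode
#' returns the mutable position with the worst (largest, under the
#' lower-is-better convention) per-residue contribution, ties broken by
#' (chain, position) order.
#'
#' @param cx A `complex_model` with non-empty mutable positions.
#' @param policy A [chooser_policy()].
#' @param contrib Named numeric vector of per-residue contributions keyed
#'   `chain:pos` (required in guided mode; must cover all mutable positions).
#' @return A list with elements `chain` and `pos`.
#' @export
choose_site <- function(cx, policy, contrib = NULL) {
  m <- cx$mutable
  if (nrow(m) == 0) stop("complex has no mutable positions", call. = FALSE)
  sites <- guided_site_order(cx, policy, contrib, n = 1L)
  if (policy$site_mode == "random") {
    i <- sample.int(nrow(m), 1L)
    return(list(chain = m$chain[i], pos = m$pos[i]))
  }
  sites[[1]]
}

# worst-first deterministic ordering of mutable sites under `contrib`;
# also validates coverage.  Returns the first `n` sites (random mode: NULL).
guided_site_order <- function(cx, policy, contrib, n) {
  if (policy$site_mode != "guided") return(NULL)
  m <- cx$mutable
  keys <- res_key(m$chain, m$pos)
  missing <- keys[!(keys %in% names(contrib))]
  if (length(missing) > 0) {
    stop(sprintf("guided site selection: no contribution supplied for position(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vals <- contrib[keys]
  ord <- order(-vals, m$chain, m$pos)
  lapply(ord[seq_len(min(n, length(ord)))],
         function(i) list(chain = m$chain[i], pos = m$pos[i]))
}

#' Choose a replacement amino acid
#'
#' Draws a residue different from `current_aa` under the policy's scheme:
#' uniform over the 19 alternatives, custom weights renormalized after
#' zeroing the current residue, or uniform within the active group minus the
#' current residue.
#'
#' @param current_aa One-letter code of the residue being replaced.
#' @param policy A [chooser_policy()].
#' @return A one-letter code, never equal to `current_aa`.
#' @export
choose_aa <- function(current_aa, policy) {
  check_aa(current_aa)
  pool <- aa_choice_set(current_aa, policy)
  if (length(pool$aa) == 0) {
    stop(sprintf("no replacement available for %s under the %s scheme",
                 current_aa, policy$aa_scheme), call. = FALSE)
  }
  pool$aa[sample.int(length(pool$aa), 1L, prob = pool$w)]
}

# admissible replacements for `current_aa` and their (unnormalized) weights
aa_choice_set <- function(current_aa, policy) {
  switch(policy$aa_scheme,
    uniform = {
      aa <- setdiff(AA20, current_aa)
      list(aa = aa, w = rep(1, length(aa)))
    },
    custom = {
      w <- policy$aa_probs
      w <- w[names(w) != current_aa & w > 0]
      list(aa = names(w), w = unname(w))
    },
    grouped = {
      aa <- setdiff(policy$groups[[policy$active_group]], current_aa)
      list(aa = aa, w = rep(1, length(aa)))
    })
}

#' Generate distinct mutation sets for an epoch's branches
#'
#' Draws `n_branches` pairwise-distinct mutation sets (each of size
#' `sites_per_mutant`, with distinct sites within a set) under the policy.
#' Distinctness is enforced by bounded resampling; when fewer distinct sets
#' exist than requested, the error reports the achievable maximum.
#'
#' @inheritParams choose_site
#' @param n_branches Number of mutation sets required (>= 1).
#' @param max_retries Consecutive duplicate draws tolerated before giving up
#'   (default 100).
#' @return List of length `n_branches`; each element a list of `mutation`s.
#' @export
generate_mutations <- function(cx, policy, n_branches, contrib = NULL,
                               max_retries = 100L) {
  n_branches <- as.integer(n_branches)
  stopifnot(n_branches >= 1L)
  m <- cx$mutable
  if (nrow(m) == 0) stop("complex has no mutable positions", call. = FALSE)
  if (policy$sites_per_mutant > nrow(m)) {
    stop(sprintf("sites_per_mutant (%d) exceeds the number of mutable positions (%d)",
                 policy$sites_per_mutant, nrow(m)), call. = FALSE)
  }
  seq_now <- binder_sequence(cx)
  guided_sites <- guided_site_order(cx, policy, contrib, n = policy$sites_per_mutant)

  draw_set <- function() {
    sites <- if (policy$site_mode == "guided") {
      guided_sites
    } else {
      idx <- sample.int(nrow(m), policy$sites_per_mutant)
      lapply(idx, function(i) list(chain = m$chain[i], pos = m$pos[i]))
    }
    lapply(sites, function(s) {
      cur <- seq_now[[res_key(s$chain, s$pos)]]
      mutation(s$chain, s$pos, cur, choose_aa(cur, policy))
    })
  }

  out <- list()
  seen <- character(0)
  fails <- 0L
  while (length(out) < n_branches) {
    ms <- tryCatch(draw_set(), error = function(e) e)
    key <- if (inherits(ms, "error")) NA_character_ else mutation_set_key(ms)
    if (!is.na(key) && !(key %in% seen)) {
      out[[length(out) + 1L]] <- ms
      seen <- c(seen, key)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= max_retries) {
        ach <- achievable_mutation_sets(cx, policy, contrib)
        stop(sprintf(paste0("cannot generate %d distinct mutation sets: ",
                            "at most %d are achievable under this policy"),
                     n_branches, max(length(out), ach, na.rm = TRUE)),
             call. = FALSE)
      }
    }
  }
  out
}

# exact count of distinct single-site mutation sets (NA for multi-site,
# where only the retry bound applies)
achievable_mutation_sets <- function(cx, policy, contrib = NULL) {
  if (policy$sites_per_mutant != 1L) return(NA_integer_)
  m <- cx$mutable
  seq_now <- binder_sequence(cx)
  if (policy$site_mode == "guided") {
    s <- guided_site_order(cx, policy, contrib, n = 1L)[[1]]
    m <- data.frame(chain = s$chain, pos = s$pos, stringsAsFactors = FALSE)
  }
  sum(vapply(seq_len(nrow(m)), function(i) {
    cur <- seq_now[[res_key(m$chain[i], m$pos[i])]]
    length(aa_choice_set(cur, policy)$aa)
  }, numeric(1)))
}
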