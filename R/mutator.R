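#' Apply mutations to a complex
#'
#' Returns a new complex whose mutated residues carry their new identities.
#' Coordinates are untouched except for the glycine special cases: mutating
#' TO glycine collapses the side pseudo-atom onto the anchor; mutating FROM
#' glycine places a pseudo-beta-carbon 1.53 Angstrom from the anchor along
#' the local outward direction (from the centroid of the two flanking
#' anchors through the residue anchor; chain-terminal residues use a
#' deterministic perpendicular of the single neighbour direction).
#' Side-chain repacking and backbone relaxation are deliberately not
#' modelled here: identity plus pseudo-atom position is all the built-in
#' scorers read, and conformational relaxation belongs to the sampler.
#'
#' @param cx A `complex_model`.
#' @param mutations List of `mutation`s (possibly empty); each must address
#'   a declared mutable position and match the current wild-type identity.
#' @return A new `complex_model`; the input is not modified.
#' @export
apply_mutation <- function(cx, mutations) {
  stopifnot(inherits(cx, "complex_model"))
  if (length(mutations) == 0) return(cx)
  r <- cx$residues
  keys <- residue_keys(cx)
  mut_keys <- paste(cx$mutable$chain, cx$mutable$pos)
  for (m in mutations) {
    stopifnot(inherits(m, "mutation"))
    if (!(paste(m$chain, m$pos) %in% mut_keys)) {
      stop(sprintf("position %s:%d is not declared mutable", m$chain, m$pos),
           call. = FALSE)
    }
    i <- match(res_key(m$chain, m$pos), keys)
    if (is.na(i)) {
      stop(sprintf("position %s:%d not found in complex", m$chain, m$pos), call. = FALSE)
    }
    if (r$aa[i] != m$wt) {
      stop(sprintf("wild-type mismatch at %s:%d: expected %s, found %s",
                   m$chain, m$pos, m$wt, r$aa[i]), call. = FALSE)
    }
    if (m$mut == "G") {
      r[i, c("sx", "sy", "sz")] <- r[i, c("ax", "ay", "az")]
    } else if (r$aa[i] == "G") {
      dir <- pseudo_cb_direction(r, i)
      r$sx[i] <- r$ax[i] + 1.53 * dir[1]
      r$sy[i] <- r$ay[i] + 1.53 * dir[2]
      r$sz[i] <- r$az[i] + 1.53 * dir[3]
    }
    r$aa[i] <- m$mut
  }
  out <- cx
  out$residues <- r
  validate_complex(out)
  out
}

# outward unit direction for a pseudo-beta-carbon at residue row `i`:
# from the centroid of the two flanking anchors (same chain) through the
# residue anchor; chain-terminal residues take a deterministic vector
# perpendicular to the single neighbour direction.
pseudo_cb_direction <- function(r, i) {
  ch <- r$chain[i]
  rows <- which(r$chain == ch)
  k <- match(i, rows)
  a <- as.numeric(r[i, c("ax", "ay", "az")])
  prev <- if (k > 1) as.numeric(r[rows[k - 1], c("ax", "ay", "az")]) else NULL
  nxt <- if (k < length(rows)) as.numeric(r[rows[k + 1], c("ax", "ay", "az")]) else NULL
  if (!is.null(prev) && !is.null(nxt)) {
    v <- a - (prev + nxt) / 2
  } else {
    nb <- if (is.null(prev)) nxt else prev
    if (is.null(nb)) {
      v <- c(1, 0, 0)  # single-residue chain: fixed axis
    } else {
      u <- a - nb
      # cross with the axis least aligned with u, giving a stable perpendicular
      axes <- diag(3)
      e <- axes[which.min(abs(u)), ]
      v <- c(u[2] * e[3] - u[3] * e[2],
             u[3] * e[1] - u[1] * e[3],
             u[1] * e[2] - u[2] * e[1])
    }
  }
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

#' Apply mutations through an external mutator adapter
#'
#' Adapter contract for plugging in full-atom mutation tools: the complex is
#' written to a PDB file, the adapter receives the file path and the
#' mutation strings and must return the path of a mutated PDB, which is read
#' back and validated (same chain partition, same residue count, mutated
#' identities applied).  A validation failure signals a broken external
#' tool, not a protocol failure.
#'
#' @param cx A `complex_model`.
#' @param mutations List of `mutation`s.
#' @param adapter Either a function `(pdb_in, mutation_strings, pdb_out) ->
#'   path`, or the name `"builtin"` for the loopback adapter (which applies
#'   [apply_mutation()] through the same file round trip).
#' @param workdir Directory for the exchanged PDB files (default a fresh
#'   temporary directory).
#' @return A validated `complex_model`.
#' @export
external_mutate <- function(cx, mutations, adapter = "builtin",
                            workdir = tempfile("mutator")) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  pdb_in <- file.path(workdir, "input.pdb")
  pdb_out <- file.path(workdir, "mutated.pdb")
  write_pdb(cx, pdb_in)
  mut_strings <- vapply(mutations, format_mutation, character(1))
  if (identical(adapter, "builtin")) {
    adapter <- function(pin, ms, pout) {
      mcx <- read_pdb(pin, binder_chains = cx$binder_chains,
                      target_chains = cx$target_chains, mutable = cx$mutable)
      write_pdb(apply_mutation(mcx, lapply(ms, parse_mutation_string)), pout)
      pout
    }
  }
  res_path <- adapter(pdb_in, mut_strings, pdb_out)
  out <- read_pdb(res_path, binder_chains = cx$binder_chains,
                  target_chains = cx$target_chains, mutable = cx$mutable)
  validate_external_mutation(cx, out, mutations)
  out
}

validate_external_mutation <- function(cx, out, mutations) {
  in_chains <- sort(unique(cx$residues$chain))
  out_chains <- sort(unique(out$residues$chain))
  gone <- setdiff(in_chains, out_chains)
  if (length(gone) > 0) {
    stop(sprintf("external mutator dropped chain(s): %s", paste(gone, collapse = ", ")),
         call. = FALSE)
  }
  if (!identical(out_chains, in_chains)) {
    stop("external mutator changed the chain set", call. = FALSE)
  }
  if (nrow(out$residues) != nrow(cx$residues)) {
    stop(sprintf("external mutator changed the residue count (%d -> %d)",
                 nrow(cx$residues), nrow(out$residues)), call. = FALSE)
  }
  expect_seq <- structure(cx$residues$aa, names = residue_keys(cx))
  for (m in mutations) expect_seq[[res_key(m$chain, m$pos)]] <- m$mut
  got_seq <- structure(out$residues$aa, names = residue_keys(out))
  cmp <- expect_seq[names(got_seq)] != got_seq
  bad <- names(got_seq)[is.na(cmp) | cmp]
  if (length(bad) > 0) {
    stop(sprintf("external mutator produced wrong residue identity at %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(out)
}
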