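SCORER_KINDS <- c("contact_potential", "screened_electrostatic",
                  "contact_count", "hidden_oracle", "external")
DECOMPOSABLE_KINDS <- c("contact_potential", "screened_electrostatic",
                        "contact_count", "hidden_oracle")

matrix_cache <- new.env(parent = emptyenv())

#' Default residue contact matrix
#'
#' The 20x20 symmetric contact potential shipped with the package
#' (`inst/extdata/contact_matrix.txt`): hydrophobic-hydrophobic contacts are
#' favourable, like-charge contacts unfavourable, opposite-charge contacts
#' favourable, polar-polar mildly favourable.  Lower is better.  Users may
#' override the matrix per scorer via [read_contact_matrix()] or a run
#' configuration.
#'
#' @return Numeric 20x20 matrix with one-letter dimnames.
#' @export
default_contact_matrix <- function() {
  if (is.null(matrix_cache$default)) {
    path <- system.file("extdata", "contact_matrix.txt", package = "evobinder")
    matrix_cache$default <- read_contact_matrix(path)
  }
  matrix_cache$default
}

#' Read a contact matrix file
#'
#' Whitespace-delimited 20-row table with a one-letter header row and
#' column; must be symmetric and cover the full canonical alphabet.
#'
#' @param path File path.
#' @return Numeric 20x20 matrix with one-letter dimnames.
#' @export
read_contact_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  check_contact_matrix(m)
  m[AA20, AA20]
}

check_contact_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(20L, 20L)) ||
      !setequal(rownames(m), AA20) || !setequal(colnames(m), AA20)) {
    stop("contact matrix must be 20x20 with one-letter row/column names",
         call. = FALSE)
  }
  m <- m[AA20, AA20]
  if (max(abs(m - t(m))) > 1e-9) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  invisible(m)
}

#' Define a scoring function
#'
#' Builds the specification of one interface scorer.  All scores follow a
#' single convention after the `sign` multiplier is applied: lower is
#' better.  Built-in kinds:
#' \describe{
#'   \item{`contact_count`}{minus the number of cross-interface side
#'     pseudo-atom contacts within `cutoff`.}
#'   \item{`contact_potential`}{sum of a 20x20 residue contact matrix over
#'     the contact pairs (default [default_contact_matrix()]).}
#'   \item{`screened_electrostatic`}{Debye-screened Coulomb sum
#'     `q_i q_j exp(-d/screen_len)/d` over contact pairs, with integer-ish
#'     residue charges (D,E: -1; K,R: +1; H: +0.5).}
#'   \item{`hidden_oracle`}{contact count plus `weight` per binder position
#'     deviating from a planted optimal sequence; the synthetic ground
#'     truth used to exercise the optimizer (see
#'     [hidden_oracle_scorer()]).}
#'   \item{`external`}{adapter contract: a function receiving a frame PDB
#'     path and returning one real number.}
#' }
#'
#' @param name Unique scorer name within a run.
#' @param kind One of the kinds above.
#' @param sign +1 or -1, applied so lower is always better.
#' @param cutoff Interface cutoff, Angstrom (default 8).
#' @param matrix Contact matrix override (contact_potential).
#' @param screen_len Debye screening length, Angstrom (default 10).
#' @param optimal_seq Named one-letter vector keyed `chain:pos`
#'   (hidden_oracle).
#' @param weight Mismatch penalty per deviating position (hidden_oracle,
#'   default 1).
#' @param adapter Function `(pdb_path) -> numeric` (external).
#' @return An object of class `scorer_spec`.
#' @export
scorer <- function(name, kind = SCORER_KINDS, sign = 1, cutoff = 8,
                   matrix = NULL, screen_len = 10, optimal_seq = NULL,
                   weight = 1, adapter = NULL) {
  kind <- match.arg(kind)
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1", call. = FALSE)
  stopifnot(cutoff > 0, screen_len > 0)
  if (kind == "contact_potential" && !is.null(matrix)) check_contact_matrix(matrix)
  if (kind == "hidden_oracle") {
    if (is.null(optimal_seq) || is.null(names(optimal_seq))) {
      stop("hidden_oracle requires a named optimal_seq", call. = FALSE)
    }
    check_aa(optimal_seq)
  }
  if (kind == "external" && !is.function(adapter)) {
    stop("external scorer requires an adapter function", call. = FALSE)
  }
  structure(list(name = as.character(name), kind = kind, sign = sign,
                 cutoff = cutoff, matrix = matrix, screen_len = screen_len,
                 optimal_seq = optimal_seq, weight = weight, adapter = adapter),
            class = "scorer_spec")
}

#' Contact-potential score of one frame
#'
#' Sum of `matrix[aa_i, aa_j]` over all cross-interface contact pairs; 0 for
#' an empty interface.
#'
#' @param cx A `complex_model` frame.
#' @param matrix Symmetric 20x20 contact matrix.
#' @param cutoff Contact cutoff, Angstrom.
#' @return Scalar score (lower is better for the default matrix).
#' @export
contact_score <- function(cx, matrix = default_contact_matrix(), cutoff = 8) {
  m <- check_contact_matrix(matrix)
  cp <- contact_pairs(cx, cutoff)
  if (nrow(cp) == 0) return(0)
  aa <- structure(cx$residues$aa, names = residue_keys(cx))
  sum(m[cbind(aa[res_key(cp$b_chain, cp$b_pos)], aa[res_key(cp$t_chain, cp$t_pos)])])
}

#' Screened electrostatic score of one frame
#'
#' Debye-screened Coulomb interaction `q_i q_j exp(-d/screen_len) / d`
#' summed over cross-interface pairs within `cutoff`; coincident
#' pseudo-atoms (d = 0) are skipped with a warning.
#'
#' @inheritParams contact_score
#' @param screen_len Screening length, Angstrom (> 0).
#' @return Scalar score; negative values favour binding.
#' @export
electro_score <- function(cx, cutoff = 8, screen_len = 10) {
  stopifnot(screen_len > 0)
  cp <- contact_pairs(cx, cutoff)
  if (nrow(cp) == 0) return(0)
  aa <- structure(cx$residues$aa, names = residue_keys(cx))
  qb <- aa_charge(aa[res_key(cp$b_chain, cp$b_pos)])
  qt <- aa_charge(aa[res_key(cp$t_chain, cp$t_pos)])
  zero <- cp$dist <= 0
  if (any(zero)) {
    warning(sprintf("skipping %d coincident pseudo-atom pair(s) at zero distance",
                    sum(zero)))
  }
  keep <- !zero
  sum(qb[keep] * qt[keep] * exp(-cp$dist[keep] / screen_len) / cp$dist[keep])
}

#' Contact-count score of one frame
#'
#' Minus the number of cross-interface contact pairs, so that a tighter
#' interface scores lower (better).
#'
#' @inheritParams contact_score
#' @return Scalar score, `-nrow(contact_pairs(cx, cutoff))`.
#' @export
contact_count_score <- function(cx, cutoff = 8) {
  -nrow(contact_pairs(cx, cutoff))
}

hidden_oracle_score <- function(cx, spec) {
  seq_now <- binder_sequence(cx)
  opt <- spec$optimal_seq
  mism <- sum(seq_now[names(opt)] != opt, na.rm = TRUE)
  contact_count_score(cx, spec$cutoff) + spec$weight * mism
}

#' Score one frame under a scorer specification
#'
#' Raw kind-specific score multiplied by the spec's sign, so lower is
#' better for every configured scorer.
#'
#' @param cx A `complex_model` frame.
#' @param spec A [scorer()] specification.
#' @return Scalar score.
#' @export
score_frame <- function(cx, spec) {
  stopifnot(inherits(spec, "scorer_spec"))
  raw <- switch(spec$kind,
    contact_potential = contact_score(cx,
      if (is.null(spec$matrix)) default_contact_matrix() else spec$matrix,
      spec$cutoff),
    screened_electrostatic = electro_score(cx, spec$cutoff, spec$screen_len),
    contact_count = contact_count_score(cx, spec$cutoff),
    hidden_oracle = hidden_oracle_score(cx, spec),
    external = {
      path <- tempfile("frame", fileext = ".pdb")
      on.exit(unlink(path))
      write_pdb(cx, path)
      as.numeric(spec$adapter(path))
    })
  spec$sign * raw
}

new_score_table <- function(per_frame) {
  structure(list(scorer_names = names(per_frame),
                 per_frame = per_frame,
                 averages = vapply(per_frame, mean, numeric(1))),
            class = "score_table")
}

#' Score an ensemble with multiple scorers
#'
#' Scores every frame independently under each scorer and records the
#' per-scorer arithmetic mean — the quantity all pruning decisions compare.
#'
#' @param ens An `ensemble` (>= 1 frame).
#' @param scorers Non-empty list of [scorer()] specifications with unique
#'   names.
#' @return An object of class `score_table` with elements `scorer_names`,
#'   `per_frame` (name -> numeric vector) and `averages` (name -> mean).
#' @export
score_ensemble <- function(ens, scorers) {
  stopifnot(inherits(ens, "ensemble"), length(scorers) >= 1,
            length(ens$frames) >= 1)
  nms <- vapply(scorers, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("scorer names must be unique", call. = FALSE)
  per_frame <- lapply(scorers, function(s) {
    vapply(ens$frames, score_frame, numeric(1), spec = s)
  })
  names(per_frame) <- nms
  new_score_table(per_frame)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d scorer(s) x %d frame(s)\n",
              length(x$scorer_names), length(x$per_frame[[1]])))
  print(round(x$averages, 4))
  invisible(x)
}

#' Per-residue decomposition of a frame score
#'
#' Splits each cross-interface pair's contribution half to each partner
#' residue; the hidden oracle additionally charges its mismatch penalty to
#' the deviating residue.  Residues outside the interface map to zero, and
#' the contributions sum back to the total frame score.  The decomposition
#' feeds guided site selection: the residue with the largest (worst)
#' contribution is the next mutation candidate.
#'
#' @param cx A `complex_model` frame.
#' @param spec A decomposable [scorer()] (any built-in kind; `external`
#'   scorers cannot be decomposed).
#' @return Named numeric vector over all residues, keyed `chain:pos`.
#' @export
per_residue_decomposition <- function(cx, spec) {
  stopifnot(inherits(spec, "scorer_spec"))
  if (!spec$kind %in% DECOMPOSABLE_KINDS) {
    stop(sprintf("scorer kind '%s' is not decomposable", spec$kind), call. = FALSE)
  }
  keys <- residue_keys(cx)
  contrib <- structure(numeric(length(keys)), names = keys)
  cp <- contact_pairs(cx, spec$cutoff)
  aa <- structure(cx$residues$aa, names = keys)
  if (nrow(cp) > 0) {
    bk <- res_key(cp$b_chain, cp$b_pos)
    tk <- res_key(cp$t_chain, cp$t_pos)
    term <- switch(spec$kind,
      contact_potential = {
        m <- if (is.null(spec$matrix)) default_contact_matrix() else
          check_contact_matrix(spec$matrix)
        m[cbind(aa[bk], aa[tk])]
      },
      screened_electrostatic = {
        keep <- cp$dist > 0
        v <- numeric(nrow(cp))
        v[keep] <- aa_charge(aa[bk][keep]) * aa_charge(aa[tk][keep]) *
          exp(-cp$dist[keep] / spec$screen_len) / cp$dist[keep]
        v
      },
      contact_count = rep(-1, nrow(cp)),
      hidden_oracle = rep(-1, nrow(cp)))
    for (i in seq_len(nrow(cp))) {
      contrib[[bk[i]]] <- contrib[[bk[i]]] + term[i] / 2
      contrib[[tk[i]]] <- contrib[[tk[i]]] + term[i] / 2
    }
  }
  if (spec$kind == "hidden_oracle") {
    opt <- spec$optimal_seq
    dev <- aa[names(opt)] != opt
    mism <- names(opt)[!is.na(dev) & dev]
    contrib[mism] <- contrib[mism] + spec$weight
  }
  spec$sign * contrib
}
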