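#' Coarse-grained binder/target complex
#'
#' Constructs the structural container used throughout the engine: each
#' residue carries one backbone anchor (the alpha-carbon) and one side-chain
#' pseudo-atom (the beta-carbon where present; glycine maps its side
#' pseudo-atom onto the anchor).  Chains are partitioned into binder chains
#' (the molecule being optimized) and target chains (the fixed partner).
#'
#' @param residues Data frame with columns `chain` (single-character label),
#'   `pos` (1-based integer, strictly increasing within a chain), `aa`
#'   (one-letter code), `ax`,`ay`,`az` (anchor coordinates, Angstrom) and
#'   `sx`,`sy`,`sz` (side pseudo-atom coordinates, Angstrom).
#' @param binder_chains,target_chains Character vectors of chain labels;
#'   disjoint and both non-empty.
#' @param mutable Data frame with columns `chain`, `pos` listing the binder
#'   positions open to mutation; defaults to every binder residue.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(residues, binder_chains, target_chains, mutable = NULL) {
  stopifnot(is.data.frame(residues))
  need <- c("chain", "pos", "aa", "ax", "ay", "az", "sx", "sy", "sz")
  miss <- setdiff(need, names(residues))
  if (length(miss) > 0) {
    stop("residues is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  residues <- residues[, need]
  residues$chain <- as.character(residues$chain)
  residues$pos <- as.integer(residues$pos)
  residues$aa <- as.character(residues$aa)
  for (cc in c("ax", "ay", "az", "sx", "sy", "sz")) {
    residues[[cc]] <- as.numeric(residues[[cc]])
  }
  rownames(residues) <- NULL
  binder_chains <- as.character(binder_chains)
  target_chains <- as.character(target_chains)
  if (is.null(mutable)) {
    sel <- residues$chain %in% binder_chains
    mutable <- data.frame(chain = residues$chain[sel], pos = residues$pos[sel],
                          stringsAsFactors = FALSE)
  }
  mutable <- data.frame(chain = as.character(mutable$chain),
                        pos = as.integer(mutable$pos), stringsAsFactors = FALSE)
  cx <- structure(list(residues = residues,
                       binder_chains = binder_chains,
                       target_chains = target_chains,
                       mutable = mutable),
                  class = "complex_model")
  validate_complex(cx)
  cx
}

#' Validate a complex model
#'
#' Checks the structural invariants: positions at least 1 and strictly
#' increasing within each chain, canonical residue identities, glycine side
#' pseudo-atoms coincident with their anchors, disjoint non-empty chain
#' partition, and mutable positions that exist on binder chains.
#'
#' @param cx A `complex_model`.
#' @return `cx`, invisibly; errors describe every violated invariant.
#' @export
validate_complex <- function(cx) {
  stopifnot(inherits(cx, "complex_model"))
  r <- cx$residues
  probs <- character(0)
  if (nrow(r) == 0) probs <- c(probs, "complex has no residues")
  check_aa(r$aa, "residue")
  if (any(r$pos < 1L)) probs <- c(probs, "residue positions must be >= 1")
  for (ch in unique(r$chain)) {
    p <- r$pos[r$chain == ch]
    if (any(diff(p) <= 0)) {
      probs <- c(probs, sprintf("positions not strictly increasing in chain %s", ch))
    }
  }
  gly <- r$aa == "G"
  if (any(gly)) {
    dev <- abs(cbind(r$sx - r$ax, r$sy - r$ay, r$sz - r$az)[gly, , drop = FALSE])
    if (any(dev > 1e-9)) {
      probs <- c(probs, "glycine side pseudo-atom must coincide with its anchor")
    }
  }
  if (length(cx$binder_chains) == 0) probs <- c(probs, "binder_chains is empty")
  if (length(cx$target_chains) == 0) probs <- c(probs, "target_chains is empty")
  if (length(intersect(cx$binder_chains, cx$target_chains)) > 0) {
    probs <- c(probs, "binder_chains and target_chains must be disjoint")
  }
  declared <- unique(r$chain)
  undef <- setdiff(c(cx$binder_chains, cx$target_chains), declared)
  if (length(undef) > 0) {
    probs <- c(probs, sprintf("chain(s) %s not present in residues", paste(undef, collapse = ", ")))
  }
  m <- cx$mutable
  if (nrow(m) > 0) {
    if (!all(m$chain %in% cx$binder_chains)) {
      probs <- c(probs, "mutable positions must lie on binder chains")
    }
    mk <- paste(m$chain, m$pos)
    rk <- paste(r$chain, r$pos)
    if (!all(mk %in% rk)) {
      probs <- c(probs, sprintf("mutable position(s) not found in structure: %s",
                                paste(setdiff(mk, rk), collapse = ", ")))
    }
  }
  if (length(probs) > 0) stop(paste(probs, collapse = "; "), call. = FALSE)
  invisible(cx)
}

res_key <- function(chain, pos) sprintf("%s:%d", chain, as.integer(pos))

residue_keys <- function(cx) res_key(cx$residues$chain, cx$residues$pos)

binder_mask <- function(cx) cx$residues$chain %in% cx$binder_chains
target_mask <- function(cx) cx$residues$chain %in% cx$target_chains

side_xyz <- function(cx) as.matrix(cx$residues[, c("sx", "sy", "sz")])
anchor_xyz <- function(cx) as.matrix(cx$residues[, c("ax", "ay", "az")])

# |binder| x |target| matrix of side pseudo-atom distances
cross_side_dist <- function(cx) {
  b <- side_xyz(cx)[binder_mask(cx), , drop = FALSE]
  t <- side_xyz(cx)[target_mask(cx), , drop = FALSE]
  if (nrow(b) == 0 || nrow(t) == 0) {
    stop("malformed partition: complex has no binder or no target residues", call. = FALSE)
  }
  d2 <- outer(rowSums(b^2), rowSums(t^2), "+") - 2 * b %*% t(t)
  sqrt(pmax(d2, 0))
}

#' Cross-interface contact pairs
#'
#' All binder-target residue pairs whose side pseudo-atoms lie within
#' `cutoff` Angstrom of each other, ordered by binder residue index then
#' target residue index.
#'
#' @param cx A `complex_model`.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return Data frame with columns `b_chain`, `b_pos`, `t_chain`, `t_pos`,
#'   `dist`; zero rows when the partners are out of range.
#' @export
contact_pairs <- function(cx, cutoff = 8) {
  stopifnot(cutoff > 0)
  d <- cross_side_dist(cx)
  bres <- cx$residues[binder_mask(cx), , drop = FALSE]
  tres <- cx$residues[target_mask(cx), , drop = FALSE]
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) > 0) hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(b_chain = bres$chain[hit[, 1]], b_pos = bres$pos[hit[, 1]],
             t_chain = tres$chain[hit[, 2]], t_pos = tres$pos[hit[, 2]],
             dist = d[hit], stringsAsFactors = FALSE)
}

#' Interface residues
#'
#' The set of residues (on either side) whose side pseudo-atom lies within
#' `cutoff` of at least one residue of the opposite partner.
#'
#' @inheritParams contact_pairs
#' @return Data frame with columns `chain`, `pos`, in residue order.
#' @export
interface_residues <- function(cx, cutoff = 8) {
  cp <- contact_pairs(cx, cutoff)
  keys <- unique(c(res_key(cp$b_chain, cp$b_pos), res_key(cp$t_chain, cp$t_pos)))
  sel <- residue_keys(cx) %in% keys
  data.frame(chain = cx$residues$chain[sel], pos = cx$residues$pos[sel],
             stringsAsFactors = FALSE)
}

#' Binder sequence of a complex
#'
#' @param cx A `complex_model`.
#' @return Named character vector of one-letter codes, names `chain:pos`.
#' @export
binder_sequence <- function(cx) {
  sel <- binder_mask(cx)
  structure(cx$residues$aa[sel],
            names = res_key(cx$residues$chain[sel], cx$residues$pos[sel]))
}

#' @export
print.complex_model <- function(x, ...) {
  nb <- sum(binder_mask(x))
  nt <- sum(target_mask(x))
  cat(sprintf("<complex_model> %d residues (binder %s: %d, target %s: %d), %d mutable\n",
              nrow(x$residues),
              paste(x$binder_chains, collapse = ","), nb,
              paste(x$target_chains, collapse = ","), nt,
              nrow(x$mutable)))
  invisible(x)
}
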