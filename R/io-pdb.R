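# PDB exchange for the coarse-grained model: reading goes through bio3d's
# parser; writing emits fixed-width wwPDB ATOM records (one CA and one CB
# pseudo-atom per residue, CB omitted for glycine), with MODEL/ENDMDL
# wrapping for ensembles.

#' Read a PDB file into a coarse-grained complex
#'
#' Parses ATOM records of the first model, extracting the alpha-carbon as
#' the residue anchor and the beta-carbon as the side pseudo-atom (anchor
#' fallback for glycine or a missing CB, with a warning).  Alternate
#' locations resolve to the highest occupancy, then altloc 'A'.  Residues
#' without a CA are skipped with a warning; non-canonical residues are
#' rejected.
#'
#' @param path PDB file path.
#' @param binder_chains,target_chains Chain partition; when both are `NULL`
#'   the first chain is the binder and the rest the target.
#' @param mutable Optional mutable-position data frame (default: every
#'   binder residue).
#' @return A `complex_model`.
#' @export
read_pdb <- function(path, binder_chains = NULL, target_chains = NULL,
                     mutable = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  residues_from_atoms(pdb$atom, path,
                      binder_chains = binder_chains,
                      target_chains = target_chains, mutable = mutable)
}

residues_from_atoms <- function(atoms, path, binder_chains, target_chains,
                                mutable, xyz_override = NULL) {
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop(sprintf("no ATOM records in %s", path), call. = FALSE)
  }
  if (!is.null(xyz_override)) {
    atoms$x <- xyz_override[, 1]; atoms$y <- xyz_override[, 2]
    atoms$z <- xyz_override[, 3]
  }
  atoms <- atoms[atoms$elety %in% c("CA", "CB"), , drop = FALSE]
  # altloc resolution: highest occupancy, then altloc 'A'; identical
  # (chain, resno, atom, altloc) duplicates signal a malformed file
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  alt <- ifelse(is.na(atoms$alt) | atoms$alt == "", " ", atoms$alt)
  full <- paste(key, alt)
  if (anyDuplicated(full)) {
    cnt <- table(full)
    stop(sprintf("duplicate atom record(s) in %s: %s", path,
                 paste(names(cnt)[cnt > 1], collapse = "; ")), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(atoms$o), 1, atoms$o)
    ord <- order(key, -occ, alt != "A", alt, method = "radix")
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  }
  chains <- unique(atoms$chain)
  rows <- list()
  for (ch in chains) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    for (rn in sort(unique(sub$resno))) {
      rs <- sub[sub$resno == rn, , drop = FALSE]
      resid <- rs$resid[1]
      aa <- AA3TO1[[resid]]
      if (is.null(aa)) {
        stop(sprintf("non-canonical residue %s at %s:%d in %s", resid, ch, rn, path),
             call. = FALSE)
      }
      ca <- rs[rs$elety == "CA", , drop = FALSE]
      cb <- rs[rs$elety == "CB", , drop = FALSE]
      if (nrow(ca) == 0) {
        warning(sprintf("residue %s:%d has no CA; skipped", ch, rn))
        next
      }
      if (nrow(cb) == 0) {
        if (aa != "G") {
          warning(sprintf("residue %s:%d (%s) has no CB; using CA as side pseudo-atom",
                          ch, rn, aa))
        }
        cb <- ca
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, pos = as.integer(rn), aa = aa,
        ax = ca$x[1], ay = ca$y[1], az = ca$z[1],
        sx = cb$x[1], sy = cb$y[1], sz = cb$z[1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop(sprintf("no usable residues in %s", path), call. = FALSE)
  residues <- do.call(rbind, rows)
  # glycine side pseudo-atom is the anchor by construction
  gly <- residues$aa == "G"
  residues[gly, c("sx", "sy", "sz")] <- residues[gly, c("ax", "ay", "az")]
  if (is.null(binder_chains) && is.null(target_chains)) {
    binder_chains <- chains[1]
    target_chains <- setdiff(chains, chains[1])
  }
  complex_model(residues, binder_chains, target_chains, mutable = mutable)
}

#' Read a multi-model PDB as an ensemble
#'
#' Each MODEL block becomes one frame; all frames must share topology.
#'
#' @inheritParams read_pdb
#' @return An `ensemble`.
#' @export
read_ensemble_pdb <- function(path, binder_chains = NULL, target_chains = NULL,
                              mutable = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  nmod <- nrow(pdb$xyz)
  frames <- lapply(seq_len(max(1, nmod)), function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    suppressWarnings(residues_from_atoms(pdb$atom, path,
                                         binder_chains = binder_chains,
                                         target_chains = target_chains,
                                         mutable = mutable,
                                         xyz_override = xyz))
  })
  new_ensemble(frames, sampler_params(n_frames = length(frames),
                                      rigid_rot_max = 0, rigid_trans_max = 0,
                                      residue_noise_sd = 0))
}

format_atom_line <- function(serial, name, resid3, chain, resno, x, y, z) {
  # wwPDB fixed columns; pseudo-atoms are carbons
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, name, resid3, chain, resno, x, y, z, 1.00, 0.00)
}

write_frame_lines <- function(cx) {
  r <- cx$residues
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(r))) {
    resid3 <- AA1TO3[[r$aa[i]]]
    serial <- serial + 1L
    lines <- c(lines, format_atom_line(serial, "CA", resid3, r$chain[i], r$pos[i],
                                       r$ax[i], r$ay[i], r$az[i]))
    if (r$aa[i] != "G") {
      serial <- serial + 1L
      lines <- c(lines, format_atom_line(serial, "CB", resid3, r$chain[i], r$pos[i],
                                         r$sx[i], r$sy[i], r$sz[i]))
    }
  }
  lines
}

#' Write a complex (or ensemble) as PDB
#'
#' Emits one CA and one CB pseudo-atom per residue (CB omitted for
#' glycine) in fixed-width wwPDB columns; an ensemble is wrapped in
#' MODEL/ENDMDL records.
#'
#' @param cx A `complex_model` (ignored when `ensemble` is given, beyond
#'   being its reference).
#' @param path Output file path.
#' @param ensemble Optional `ensemble` for multi-model output.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(cx, path, ensemble = NULL) {
  if (is.null(ensemble)) {
    lines <- c(write_frame_lines(cx), "END")
  } else {
    lines <- character(0)
    for (k in seq_along(ensemble$frames)) {
      lines <- c(lines, sprintf("MODEL     %4d", k),
                 write_frame_lines(ensemble$frames[[k]]), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}
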