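#' Sampler parameters
#'
#' Controls the built-in stochastic conformational sampler, which stands in
#' for molecular-dynamics relaxation at coarse grain.  Each frame beyond the
#' first applies (i) a random rigid rotation of the binder about its
#' centroid, (ii) a random rigid translation of the binder, then (iii)
#' independent isotropic Gaussian jitter to every pseudo-atom of both
#' partners.  Restrained mode scales all three amplitudes by
#' `restraint_factor`, emulating positional restraints that keep the bound
#' pose intact during early optimization.
#'
#' @param n_frames Ensemble size including the unperturbed input frame
#'   (default 10).
#' @param rigid_rot_max Maximum binder rotation angle, degrees (default 5).
#' @param rigid_trans_max Maximum binder translation, Angstrom (default 1).
#' @param residue_noise_sd Per-coordinate Gaussian jitter, Angstrom
#'   (default 0.3).
#' @param restrained Logical; apply the restraint scaling (default FALSE).
#' @param restraint_factor Amplitude multiplier in (0, 1] used when
#'   restrained (default 0.2).
#' @return An object of class `sampler_params`.
#' @export
sampler_params <- function(n_frames = 10L, rigid_rot_max = 5,
                           rigid_trans_max = 1, residue_noise_sd = 0.3,
                           restrained = FALSE, restraint_factor = 0.2) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  stopifnot(rigid_rot_max >= 0, rigid_trans_max >= 0, residue_noise_sd >= 0,
            restraint_factor > 0, restraint_factor <= 1)
  structure(list(n_frames = n_frames, rigid_rot_max = rigid_rot_max,
                 rigid_trans_max = rigid_trans_max,
                 residue_noise_sd = residue_noise_sd,
                 restrained = isTRUE(restrained),
                 restraint_factor = restraint_factor),
            class = "sampler_params")
}

new_ensemble <- function(frames, params, seed_record = NA_integer_) {
  structure(list(frames = frames, params = params, seed_record = seed_record),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames of %d residues\n",
              length(x$frames), nrow(x$frames[[1]]$residues)))
  invisible(x)
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
rotation_matrix <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_unit_vector <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

#' Sample a conformational ensemble by rigid-body jitter
#'
#' Frame 1 is always the unperturbed input complex, so every ensemble
#' contains the reference pose; frames 2..n apply the stochastic
#' perturbation described in [sampler_params()].  Glycine side pseudo-atoms
#' are re-pinned to their anchors after jitter.  Randomness comes from the
#' session RNG: seed beforehand (or via the optimizer's substreams) for
#' reproducibility.
#'
#' @param cx A `complex_model`.
#' @param params A [sampler_params()].
#' @return An `ensemble` whose frames share sequence and chain topology
#'   with `cx`.
#' @export
jitter_sample <- function(cx, params) {
  stopifnot(inherits(cx, "complex_model"), inherits(params, "sampler_params"))
  f <- if (params$restrained) params$restraint_factor else 1
  rot_max <- params$rigid_rot_max * pi / 180 * f
  trans_max <- params$rigid_trans_max * f
  noise_sd <- params$residue_noise_sd * f
  bsel <- binder_mask(cx)
  frames <- vector("list", params$n_frames)
  frames[[1]] <- cx
  for (k in seq_len(params$n_frames)[-1]) {
    r <- cx$residues
    A <- as.matrix(r[, c("ax", "ay", "az")])
    S <- as.matrix(r[, c("sx", "sy", "sz")])
    # rigid move of the binder about its pseudo-atom centroid
    axis <- random_unit_vector()
    theta <- runif(1, 0, rot_max)
    tdir <- random_unit_vector()
    tmag <- runif(1, 0, trans_max)
    if (theta > 0 || tmag > 0) {
      ctr <- colMeans(rbind(A[bsel, , drop = FALSE], S[bsel, , drop = FALSE]))
      R <- rotation_matrix(axis, theta)
      move <- function(M) sweep(sweep(M, 2, ctr) %*% t(R), 2, ctr + tmag * tdir, "+")
      A[bsel, ] <- move(A[bsel, , drop = FALSE])
      S[bsel, ] <- move(S[bsel, , drop = FALSE])
    }
    # isotropic jitter on every pseudo-atom of both partners
    if (noise_sd > 0) {
      A <- A + matrix(rnorm(length(A), sd = noise_sd), ncol = 3)
      S <- S + matrix(rnorm(length(S), sd = noise_sd), ncol = 3)
    } else {
      # burn the same number of draws so frame geometry is the only thing
      # that changes when noise_sd is zero
      rnorm(2 * length(A))
    }
    gly <- r$aa == "G"
    S[gly, ] <- A[gly, , drop = FALSE]
    r[, c("ax", "ay", "az")] <- A
    r[, c("sx", "sy", "sz")] <- S
    fr <- cx
    fr$residues <- r
    frames[[k]] <- fr
  }
  new_ensemble(frames, params)
}

#' Mean binder-centroid displacement of an ensemble
#'
#' Average distance of the binder pseudo-atom centroid of frames 2..n from
#' that of the reference frame; a scalar summary of how far sampling moved
#' the binder, used to monitor the restrained/unrestrained phases.
#'
#' @param ens An `ensemble`.
#' @return Non-negative scalar (0 for a single-frame ensemble).
#' @export
ensemble_displacement <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  if (length(ens$frames) < 2) return(0)
  ctr <- function(cx) {
    b <- binder_mask(cx)
    colMeans(rbind(anchor_xyz(cx)[b, , drop = FALSE],
                   side_xyz(cx)[b, , drop = FALSE]))
  }
  ref <- ctr(ens$frames[[1]])
  mean(vapply(ens$frames[-1], function(f) sqrt(sum((ctr(f) - ref)^2)), numeric(1)))
}

#' Sample through an external sampler adapter
#'
#' Adapter contract for plugging in a molecular-dynamics engine: the complex
#' is written to a PDB file, the adapter must return the path of a
#' multi-model PDB, which is read back as an ensemble and validated for
#' topology match (same chains, residue count and sequence as the input).
#'
#' @param cx A `complex_model`.
#' @param adapter Either a function `(pdb_in, pdb_out) -> path` or
#'   `"loopback"`, which returns the input pose as a single frame.
#' @param workdir Directory for the exchanged files.
#' @return A validated `ensemble`.
#' @export
external_sample <- function(cx, adapter = "loopback", workdir = tempfile("sampler")) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  pdb_in <- file.path(workdir, "input.pdb")
  pdb_out <- file.path(workdir, "ensemble.pdb")
  write_pdb(cx, pdb_in)
  if (identical(adapter, "loopback")) {
    adapter <- function(pin, pout) { file.copy(pin, pout, overwrite = TRUE); pout }
  }
  res_path <- adapter(pdb_in, pdb_out)
  ens <- read_ensemble_pdb(res_path, binder_chains = cx$binder_chains,
                           target_chains = cx$target_chains, mutable = cx$mutable)
  for (fr in ens$frames) {
    if (!identical(sort(unique(fr$residues$chain)), sort(unique(cx$residues$chain)))) {
      stop("external sampler changed the chain set", call. = FALSE)
    }
    if (nrow(fr$residues) != nrow(cx$residues) ||
        !identical(fr$residues$aa, cx$residues$aa)) {
      stop("external sampler changed the residue topology", call. = FALSE)
    }
  }
  ens
}
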