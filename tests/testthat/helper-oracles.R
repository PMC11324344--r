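# Independent brute-force oracles: straightforward double loops, kept free
# of the package's vectorized internals so they can arbitrate them.

brute_pairs <- function(cx, cutoff) {
  r <- cx$residues
  b <- which(r$chain %in% cx$binder_chains)
  t <- which(r$chain %in% cx$target_chains)
  out <- list()
  for (i in b) {
    for (j in t) {
      d <- sqrt((r$sx[i] - r$sx[j])^2 + (r$sy[i] - r$sy[j])^2 +
                  (r$sz[i] - r$sz[j])^2)
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          b_chain = r$chain[i], b_pos = r$pos[i],
          t_chain = r$chain[j], t_pos = r$pos[j], dist = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(b_chain = character(0), b_pos = integer(0),
                      t_chain = character(0), t_pos = integer(0),
                      dist = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

brute_contact_score <- function(cx, m, cutoff) {
  cp <- brute_pairs(cx, cutoff)
  r <- cx$residues
  aa_at <- function(ch, p) r$aa[r$chain == ch & r$pos == p]
  tot <- 0
  for (i in seq_len(nrow(cp))) {
    tot <- tot + m[aa_at(cp$b_chain[i], cp$b_pos[i]),
                   aa_at(cp$t_chain[i], cp$t_pos[i])]
  }
  tot
}

brute_electro_score <- function(cx, cutoff, screen_len) {
  q <- c(D = -1, E = -1, K = 1, R = 1, H = 0.5)
  chg <- function(a) if (a %in% names(q)) q[[a]] else 0
  cp <- brute_pairs(cx, cutoff)
  r <- cx$residues
  aa_at <- function(ch, p) r$aa[r$chain == ch & r$pos == p]
  tot <- 0
  for (i in seq_len(nrow(cp))) {
    if (cp$dist[i] > 0) {
      tot <- tot + chg(aa_at(cp$b_chain[i], cp$b_pos[i])) *
        chg(aa_at(cp$t_chain[i], cp$t_pos[i])) *
        exp(-cp$dist[i] / screen_len) / cp$dist[i]
    }
  }
  tot
}

# random score table over given scorers: averages drawn directly
random_score_table <- function(scorers, n_frames = 3) {
  per_frame <- lapply(scorers, function(s) rnorm(n_frames, sd = 3))
  names(per_frame) <- scorers
  evobinder:::new_score_table(per_frame)
}

# apply one rigid transformation to every pseudo-atom of the complex
rigid_transform <- function(cx, angle = 0.7, axis = c(0, 0, 1), shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  r <- cx$residues
  A <- as.matrix(r[, c("ax", "ay", "az")]) %*% t(R)
  S <- as.matrix(r[, c("sx", "sy", "sz")]) %*% t(R)
  r[, c("ax", "ay", "az")] <- sweep(A, 2, shift, "+")
  r[, c("sx", "sy", "sz")] <- sweep(S, 2, shift, "+")
  out <- cx
  out$residues <- r
  out
}

# a minimal hand-built two-residue complex at controllable separation
tiny_complex <- function(sep = 5, aa_b = "L", aa_t = "F") {
  res <- data.frame(
    chain = c("A", "A", "A", "B", "B", "B"),
    pos = c(1L, 2L, 3L, 1L, 2L, 3L),
    aa = c("A", aa_b, "A", "A", aa_t, "A"),
    ax = c(-3.8, 0, 3.8, -3.8, 0, 3.8),
    ay = c(0, 0, 0, sep + 100, sep, sep + 100),
    az = 0, stringsAsFactors = FALSE)
  res$sx <- res$ax; res$sy <- res$ay; res$sz <- res$az
  complex_model(res, "A", "B")
}
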