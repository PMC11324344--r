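# Synthetic fixtures: toy binder/target complexes with idealized geometry
# and a hidden ground-truth scorer, so the whole optimization protocol is
# testable without any real structure.

#' Build a toy binder/target complex
#'
#' Two chains (binder `A`, target `B`) in an idealized geometry, facing
#' across `interface_gap`: consecutive anchors 3.8 Angstrom apart (the CA
#' virtual bond length), side pseudo-atoms pointing toward the partner.
#' Sequences are random but seeded; every binder position is mutable.
#' Geometries: `two_strands` (parallel extended chains), `two_helices`
#' (parallel ideal helices), `random_blob` (seeded compact clouds, gap
#' approximate).  The closest cross-interface side-side distance is placed
#' at `interface_gap` (exact for strands, iteratively adjusted for the
#' curved and random geometries; glycine side pseudo-atoms sit on their
#' anchors and can only widen the gap).
#'
#' @param n_binder,n_target Residue counts (>= 3).
#' @param geometry `"two_strands"`, `"two_helices"` or `"random_blob"`.
#' @param interface_gap Closest cross-interface side-side distance,
#'   Angstrom (> 0, default 5).
#' @param seed Integer seed; equal seeds give identical complexes.
#' @return A `complex_model`.
#' @export
make_toy_complex <- function(n_binder = 10L, n_target = 10L,
                             geometry = c("two_strands", "two_helices", "random_blob"),
                             interface_gap = 5, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_binder >= 3L, n_target >= 3L, interface_gap > 0)
  with_substream(as.integer(seed), {
    build_chain <- function(n, chain) {
      aa <- sample(AA20, n, replace = TRUE)
      if (geometry == "two_strands") {
        ax <- 3.8 * (seq_len(n) - 1); ay <- rep(0, n); az <- rep(0, n)
        sx <- ax; sy <- ay + 1.5; sz <- az
      } else if (geometry == "two_helices") {
        t <- (seq_len(n) - 1) * 100 * pi / 180
        ax <- (seq_len(n) - 1) * 1.5; ay <- 2.3 * cos(t); az <- 2.3 * sin(t)
        # side pseudo-atoms radially outward from the helix axis
        sx <- ax; sy <- ay * (1 + 1.5 / 2.3); sz <- az * (1 + 1.5 / 2.3)
      } else {
        ax <- cumsum(c(0, runif(n - 1, 1.5, 3.8)))
        ay <- runif(n, -3, 3); az <- runif(n, -3, 3)
        u <- matrix(stats::rnorm(3 * n), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        sx <- ax + 1.5 * u[, 1]; sy <- ay + 1.5 * u[, 2]; sz <- az + 1.5 * u[, 3]
      }
      data.frame(chain = chain, pos = seq_len(n), aa = aa,
                 ax = ax, ay = ay, az = az, sx = sx, sy = sy, sz = sz,
                 stringsAsFactors = FALSE)
    }
    b <- build_chain(n_binder, "A")
    t <- build_chain(n_target, "B")
    # mirror the target so side pseudo-atoms face the binder, then separate
    # along y until the closest side-side distance equals the gap
    flip <- function(df) {
      df$sy <- 2 * df$ay - df$sy
      df
    }
    b_s <- as.matrix(b[, c("sx", "sy", "sz")])
    place <- function(off) {
      tt <- flip(t)
      tt[, c("ay", "sy")] <- tt[, c("ay", "sy")] + off
      tt
    }
    min_gap <- function(off) {
      ts <- as.matrix(place(off)[, c("sx", "sy", "sz")])
      d2 <- outer(rowSums(b_s^2), rowSums(ts^2), "+") - 2 * b_s %*% t(ts)
      sqrt(max(min(d2), 0))
    }
    # closest pair approach: iterate the separation until the minimum
    # distance matches the gap (monotone once the chains are disjoint in y)
    off <- max(b$sy) - min(flip(t)$sy) + interface_gap
    for (it in 1:30) {
      g <- min_gap(off)
      if (abs(g - interface_gap) < 1e-9) break
      off <- off + (interface_gap - g)
    }
    tt <- place(off)
    res <- rbind(b, tt)
    gly <- res$aa == "G"
    res[gly, c("sx", "sy", "sz")] <- res[gly, c("ax", "ay", "az")]
    complex_model(res, binder_chains = "A", target_chains = "B")
  })
}

#' Hidden-oracle scorer with a planted optimal sequence
#'
#' A synthetic ground-truth scoring function for exercising the optimizer:
#' frame score = contact-count score + `weight` for every binder position
#' whose residue deviates from `optimal_seq`.  Lower is better and the
#' global minimum over sequences is attained exactly at the planted
#' sequence, while the contact term keeps the score frame-dependent like a
#' genuine structural scorer.
#'
#' @param optimal_seq Named one-letter vector keyed `chain:pos`, covering
#'   the binder positions that define the optimum (typically the interface).
#' @param weight Penalty per deviating position (default 1, comparable to
#'   one contact).
#' @param cutoff Contact cutoff for the structural term (default 8).
#' @param name Scorer name (default `"oracle"`).
#' @return A [scorer()] specification of kind `hidden_oracle`.
#' @export
hidden_oracle_scorer <- function(optimal_seq, weight = 1, cutoff = 8,
                                 name = "oracle") {
  scorer(name, "hidden_oracle", optimal_seq = optimal_seq, weight = weight,
         cutoff = cutoff)
}

#' Plant suboptimal residues into a complex
#'
#' Mutates exactly `k_sites` of the positions covered by `optimal_seq` away
#' from their optimal identity (seeded choice of sites and wrong residues),
#' producing a starting point at known Hamming distance from the planted
#' optimum.  Glycine is excluded both as a source and as a planted identity
#' so the perturbation changes sequence only, leaving the contact geometry
#' untouched.
#'
#' @param cx A `complex_model` currently matching `optimal_seq`.
#' @param optimal_seq Named one-letter vector keyed `chain:pos`.
#' @param k_sites Number of positions to corrupt (<= eligible positions).
#' @param seed Integer seed.
#' @return A new `complex_model` at Hamming distance `k_sites` from the
#'   optimum.
#' @export
plant_suboptimal <- function(cx, optimal_seq, k_sites, seed = 1L) {
  seq_now <- binder_sequence(cx)
  eligible <- names(optimal_seq)[optimal_seq != "G" &
                                 seq_now[names(optimal_seq)] == optimal_seq]
  if (k_sites > length(eligible)) {
    stop(sprintf("k_sites (%d) exceeds the %d eligible optimal positions",
                 k_sites, length(eligible)), call. = FALSE)
  }
  if (k_sites == 0) return(cx)
  with_substream(as.integer(seed), {
    sites <- sample(eligible, k_sites)
    muts <- lapply(sites, function(key) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      cur <- seq_now[[key]]
      wrong <- sample(setdiff(AA20, c(cur, "G")), 1)
      mutation(parts[1], as.integer(parts[2]), cur, wrong)
    })
    apply_mutation(cx, muts)
  })
}
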