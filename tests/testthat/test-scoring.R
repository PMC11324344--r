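test_that("contact potential sums matrix entries over the interface", {
  far <- tiny_complex(sep = 100)
  expect_equal(contact_score(far, cutoff = 8), 0)
  m <- default_contact_matrix()
  near <- tiny_complex(sep = 5, aa_b = "L", aa_t = "F")
  # pairs within 8 A: (A2,B2) at 5, plus the A-A diagonal pairs at sqrt(5^2+3.8^2)
  expect_equal(contact_score(near, cutoff = 8),
               brute_contact_score(near, m, 8), tolerance = 1e-12)
  # single-pair case against the matrix entry
  expect_equal(contact_score(near, cutoff = 5.1) -
                 m["L", "F"], brute_contact_score(near, m, 5.1) - m["L", "F"],
               tolerance = 1e-12)
  # asymmetric matrices are rejected at construction
  bad <- m; bad["A", "C"] <- bad["A", "C"] + 1
  expect_error(scorer("x", "contact_potential", matrix = bad), "symmetric")
})

test_that("screened electrostatics matches the closed form and skips coincident atoms", {
  cx <- tiny_complex(sep = 5, aa_b = "D", aa_t = "K")
  # only the D-K pair carries charge: (-1)(+1) e^{-0.5} / 5
  expect_equal(electro_score(cx, cutoff = 8, screen_len = 10),
               -exp(-0.5) / 5, tolerance = 1e-9)
  expect_equal(-exp(-0.5) / 5, -0.12131, tolerance = 5e-5)
  neutral <- tiny_complex(sep = 5, aa_b = "L", aa_t = "F")
  expect_equal(electro_score(neutral, 8, 10), 0)
  # coincident pseudo-atoms are skipped with a warning, not an error
  cx0 <- tiny_complex(sep = 5, aa_b = "D", aa_t = "K")
  cx0$residues[5, c("sx", "sy", "sz")] <- cx0$residues[2, c("sx", "sy", "sz")]
  expect_warning(v <- electro_score(cx0, 8, 10), "coincident")
  expect_true(is.finite(v))
})

test_that("all three built-in scorers equal their brute-force oracles on random complexes", {
  m <- default_contact_matrix()
  for (seed in 1:6) {
    cx <- make_toy_complex(20, 20, "random_blob", interface_gap = 4, seed = seed)
    for (cutoff in c(6, 9)) {
      expect_equal(contact_score(cx, m, cutoff), brute_contact_score(cx, m, cutoff),
                   tolerance = 1e-9)
      expect_equal(electro_score(cx, cutoff, 10),
                   brute_electro_score(cx, cutoff, 10), tolerance = 1e-9)
      expect_equal(contact_count_score(cx, cutoff), -nrow(brute_pairs(cx, cutoff)))
    }
  }
})

test_that("scores are invariant under rigid transformation of the whole complex", {
  cx <- make_toy_complex(15, 15, "two_helices", interface_gap = 5, seed = 3)
  moved <- rigid_transform(cx, angle = 0.9, axis = c(2, -1, 1), shift = c(10, 5, -3))
  for (sc in list(scorer("cc", "contact_count"),
                  scorer("cp", "contact_potential"),
                  scorer("el", "screened_electrostatic"))) {
    expect_equal(score_frame(moved, sc), score_frame(cx, sc), tolerance = 1e-9)
  }
})

test_that("ensemble scoring averages per scorer and is frame-order invariant", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 4)
  set.seed(5)
  ens <- jitter_sample(cx, sampler_params(n_frames = 5))
  scs <- list(scorer("cc", "contact_count"), scorer("el", "screened_electrostatic"))
  st <- score_ensemble(ens, scs)
  for (s in st$scorer_names) {
    expect_equal(st$averages[[s]], mean(st$per_frame[[s]]), tolerance = 1e-12)
    expect_gte(st$averages[[s]], min(st$per_frame[[s]]))
    expect_lte(st$averages[[s]], max(st$per_frame[[s]]))
  }
  # permuting the frames leaves the averages unchanged
  perm <- ens
  perm$frames <- ens$frames[c(3, 1, 5, 2, 4)]
  expect_equal(score_ensemble(perm, scs)$averages, st$averages, tolerance = 1e-12)
  # one frame: average equals the frame score
  one <- ens; one$frames <- ens$frames[1]
  st1 <- score_ensemble(one, scs)
  expect_equal(st1$averages[["cc"]], st1$per_frame[["cc"]][1])
})

test_that("the sign multiplier makes lower always better", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 6)
  plus <- scorer("s", "contact_count", sign = 1)
  minus <- scorer("s", "contact_count", sign = -1)
  expect_equal(score_frame(cx, minus), -score_frame(cx, plus))
  expect_error(scorer("s", "contact_count", sign = 2), "sign")
})

test_that("per-residue decomposition conserves the total and feeds guided selection", {
  for (seed in c(2, 8)) {
    cx <- make_toy_complex(15, 15, "random_blob", interface_gap = 4, seed = seed)
    for (sc in list(scorer("cc", "contact_count"),
                    scorer("cp", "contact_potential"),
                    scorer("el", "screened_electrostatic"))) {
      dec <- per_residue_decomposition(cx, sc)
      expect_equal(sum(dec), score_frame(cx, sc), tolerance = 1e-9)
      # residues outside the interface contribute exactly zero
      iface <- paste(interface_residues(cx, sc$cutoff)$chain,
                     interface_residues(cx, sc$cutoff)$pos, sep = ":")
      expect_true(all(dec[setdiff(names(dec), iface)] == 0))
    }
  }
  # a single pair splits half-and-half
  cx1 <- tiny_complex(sep = 5, aa_b = "D", aa_t = "K")
  el <- scorer("el", "screened_electrostatic", cutoff = 5.1)
  dec <- per_residue_decomposition(cx1, el)
  tot <- score_frame(cx1, el)
  expect_equal(dec[["A:2"]], tot / 2, tolerance = 1e-12)
  expect_equal(dec[["B:2"]], tot / 2, tolerance = 1e-12)
  # non-decomposable scorers are refused
  ext <- scorer("x", "external", adapter = function(p) 0)
  expect_error(per_residue_decomposition(cx1, ext), "not decomposable")
})

test_that("unknown scorer kinds are rejected when the configuration is built", {
  expect_error(scorer("bad", "not_a_kind"), "arg")
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(c("input_pdb: none.pdb",
               "scorers:",
               "  - name: weird",
               "    kind: quantum_affinity"), cfgfile)
  expect_error(load_config(cfgfile), "quantum_affinity")
})
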