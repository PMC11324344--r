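test_that("applying an empty mutation set is the identity", {
  cx <- make_toy_complex(6, 6, "two_strands", interface_gap = 5, seed = 1)
  expect_identical(apply_mutation(cx, list()), cx)
})

test_that("a single substitution changes exactly one residue and no coordinates", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 5)
  sq <- binder_sequence(cx)
  key <- names(sq)[3]
  cur <- sq[[key]]
  new_aa <- setdiff(AA20, c(cur, "G"))[1]
  pos <- as.integer(sub(".*:", "", key))
  m <- mutation("A", pos, cur, new_aa)
  out <- apply_mutation(cx, list(m))
  changed <- which(out$residues$aa != cx$residues$aa)
  expect_length(changed, 1)
  expect_equal(out$residues$aa[changed], new_aa)
  coords <- c("ax", "ay", "az", "sx", "sy", "sz")
  expect_identical(out$residues[, coords], cx$residues[, coords])
  # input untouched (pure function), repeated application bit-identical
  expect_equal(binder_sequence(cx), sq)
  expect_identical(apply_mutation(cx, list(m)), out)
})

test_that("sequence Hamming distance equals the number of mutations applied", {
  cx <- make_toy_complex(12, 8, "two_strands", interface_gap = 5, seed = 6)
  sq <- binder_sequence(cx)
  picks <- c(2, 5, 9)
  muts <- lapply(picks, function(i) {
    key <- names(sq)[i]
    mutation("A", as.integer(sub(".*:", "", key)), sq[[i]],
             setdiff(AA20, c(sq[[i]], "G"))[2])
  })
  out <- apply_mutation(cx, muts)
  expect_equal(sum(binder_sequence(out) != sq), 3)
})

test_that("glycine round trip restores the side pseudo-atom 1.53 A from the anchor", {
  cx <- make_toy_complex(10, 10, "two_strands", interface_gap = 5, seed = 7)
  sq <- binder_sequence(cx)
  key <- names(sq)[4]
  pos <- as.integer(sub(".*:", "", key))
  cur <- sq[[key]]
  if (cur == "G") {
    cur2 <- "W"
    cx <- apply_mutation(cx, list(mutation("A", pos, "G", cur2)))
    cur <- cur2
  }
  if (cur != "W") {
    cx <- apply_mutation(cx, list(mutation("A", pos, cur, "W")))
  }
  to_g <- apply_mutation(cx, list(mutation("A", pos, "W", "G")))
  i <- which(to_g$residues$chain == "A" & to_g$residues$pos == pos)
  expect_equal(as.numeric(to_g$residues[i, c("sx", "sy", "sz")]),
               as.numeric(to_g$residues[i, c("ax", "ay", "az")]))
  back <- apply_mutation(to_g, list(mutation("A", pos, "G", "W")))
  expect_identical(binder_sequence(back)[[key]], "W")
  d <- sqrt(sum((as.numeric(back$residues[i, c("sx", "sy", "sz")]) -
                   as.numeric(back$residues[i, c("ax", "ay", "az")]))^2))
  expect_equal(d, 1.53, tolerance = 1e-6)
})

test_that("pseudo-CB placement from glycine is rotation-covariant", {
  cx <- make_toy_complex(8, 8, "two_helices", interface_gap = 5, seed = 8)
  sq <- binder_sequence(cx)
  key <- names(sq)[3]; pos <- as.integer(sub(".*:", "", key)); cur <- sq[[key]]
  if (cur != "G") cx <- apply_mutation(cx, list(mutation("A", pos, cur, "G")))
  grow <- function(c0) apply_mutation(c0, list(mutation("A", pos, "G", "M")))
  a <- grow(cx)
  b <- grow(rigid_transform(cx, angle = 1.1, axis = c(1, 2, 3), shift = c(-4, 2, 7)))
  bt <- rigid_transform(a, angle = 1.1, axis = c(1, 2, 3), shift = c(-4, 2, 7))
  i <- which(a$residues$chain == "A" & a$residues$pos == pos)
  expect_equal(as.numeric(b$residues[i, c("sx", "sy", "sz")]),
               as.numeric(bt$residues[i, c("sx", "sy", "sz")]), tolerance = 1e-9)
})

test_that("wild-type mismatches and non-mutable positions are rejected", {
  cx <- make_toy_complex(6, 6, "two_strands", interface_gap = 5, seed = 9)
  sq <- binder_sequence(cx)
  pos <- as.integer(sub(".*:", "", names(sq)[1]))
  wrong_wt <- setdiff(AA20, sq[[1]])[1]
  expect_error(apply_mutation(cx, list(mutation("A", pos, wrong_wt,
                                                setdiff(AA20, c(wrong_wt, sq[[1]]))[1]))),
               "expected")
  cx$mutable <- cx$mutable[-1, , drop = FALSE]
  expect_error(apply_mutation(cx, list(mutation("A", pos, sq[[1]],
                                                setdiff(AA20, sq[[1]])[1]))),
               "not declared mutable")
})

test_that("the external mutator contract validates its adapter's output", {
  cx <- make_toy_complex(6, 6, "two_strands", interface_gap = 5, seed = 10)
  sq <- binder_sequence(cx)
  pos <- as.integer(sub(".*:", "", names(sq)[2]))
  mut_aa <- setdiff(AA20, c(sq[[2]], "G"))[1]
  muts <- list(mutation("A", pos, sq[[2]], mut_aa))
  # loopback adapter reproduces the built-in mutator through a PDB round trip
  loop <- external_mutate(cx, muts, adapter = "builtin")
  direct <- apply_mutation(cx, muts)
  expect_equal(binder_sequence(loop), binder_sequence(direct))
  expect_equal(loop$residues[, c("ax", "ay", "az")],
               direct$residues[, c("ax", "ay", "az")], tolerance = 1e-3)
  # adapter ignoring the mutation fails identity validation
  lazy <- function(pin, ms, pout) { file.copy(pin, pout, overwrite = TRUE); pout }
  expect_error(external_mutate(cx, muts, adapter = lazy), "wrong residue identity")
  # adapter dropping a chain names the chain
  drop_b <- function(pin, ms, pout) {
    lines <- readLines(pin)
    keep <- !(startsWith(lines, "ATOM") & substr(lines, 22, 22) == "B")
    writeLines(lines[keep], pout)
    pout
  }
  expect_error(external_mutate(cx, muts, adapter = drop_b), "chain")
})
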