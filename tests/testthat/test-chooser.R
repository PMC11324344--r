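make_site_complex <- function(n = 4) {
  make_toy_complex(max(n, 3), 5, "two_strands", interface_gap = 5, seed = 2)
}

test_that("guided site selection returns the worst contributor with lexicographic ties", {
  cx <- make_toy_complex(5, 5, "two_strands", interface_gap = 5, seed = 1)
  cx$mutable <- data.frame(chain = "A", pos = c(1L, 3L, 5L))
  contrib <- c("A:1" = -3.0, "A:3" = 1.5, "A:5" = -0.2)
  pol <- chooser_policy("guided")
  s <- choose_site(cx, pol, contrib)
  expect_equal(s$pos, 3L)
  # ties break on (chain, position) order
  contrib2 <- c("A:1" = 1.5, "A:3" = 1.5, "A:5" = -0.2)
  expect_equal(choose_site(cx, pol, contrib2)$pos, 1L)
  # missing coverage is an error naming the hole
  expect_error(choose_site(cx, pol, contrib[-2]), "A:3")
  # a single mutable site is returned under any mode
  cx$mutable <- data.frame(chain = "A", pos = 2L)
  set.seed(1)
  expect_equal(choose_site(cx, chooser_policy("random"))$pos, 2L)
  expect_equal(choose_site(cx, pol, c("A:2" = 0))$pos, 2L)
})

test_that("random site draws are uniform over the mutable positions", {
  cx <- make_site_complex(4)
  cx$mutable <- data.frame(chain = "A", pos = 1:4)
  pol <- chooser_policy("random")
  set.seed(99)
  draws <- replicate(40000, choose_site(cx, pol)$pos)
  freq <- table(factor(draws, levels = 1:4)) / 40000
  expect_true(all(abs(freq - 0.25) < 0.01))  # 3 binomial sigma ~ 0.0065
})

test_that("replacement draws follow the configured scheme and never return the current residue", {
  # grouped with a two-member group is deterministic
  pol_g <- chooser_policy(aa_scheme = "grouped", active_group = "negative")
  set.seed(1)
  expect_identical(replicate(20, choose_aa("D", pol_g)), rep("E", 20))
  expect_error(chooser_policy(aa_scheme = "grouped", active_group = "nope"),
               "active_group")
  # a singleton choice set after excluding the current residue errors
  pol_one <- chooser_policy(aa_scheme = "grouped",
                            groups = list(solo = "W"), active_group = "solo")
  expect_error(choose_aa("W", pol_one), "no replacement")
  # custom point mass
  pol_c <- chooser_policy(aa_scheme = "custom",
                          aa_probs = c(W = 1, A = 0, L = 0))
  set.seed(2)
  expect_identical(replicate(10, choose_aa("A", pol_c)), rep("W", 10))
  # never the current residue, any scheme
  set.seed(3)
  for (pol in list(chooser_policy(), pol_g,
                   chooser_policy(aa_scheme = "custom",
                                  aa_probs = c(A = 1, D = 2, E = 3, W = 1)))) {
    for (cur in c("A", "D", "E")) {
      expect_false(cur %in% replicate(50, choose_aa(cur, pol)))
    }
  }
})

test_that("uniform replacement frequencies match the 1/19 binomial oracle", {
  set.seed(7)
  draws <- replicate(19000, choose_aa("G", chooser_policy()))
  freq <- table(factor(draws, levels = setdiff(AA20, "G"))) / 19000
  p <- 1 / 19
  sigma3 <- 3 * sqrt(p * (1 - p) / 19000)
  expect_true(all(abs(freq - p) < sigma3))
  # chi-square goodness of fit at alpha = 0.001
  expect_gt(chisq.test(table(factor(draws, levels = setdiff(AA20, "G"))))$p.value,
            0.001)
})

test_that("custom replacement frequencies converge to the renormalized weights", {
  w <- c(W = 4, F = 2, Y = 1, L = 1)
  pol <- chooser_policy(aa_scheme = "custom", aa_probs = w)
  set.seed(11)
  draws <- replicate(10000, choose_aa("A", pol))
  obs <- table(factor(draws, levels = names(w)))
  expect_gt(chisq.test(obs, p = w / sum(w))$p.value, 0.001)
  # zeroing the current residue renormalizes over the rest
  set.seed(12)
  draws2 <- replicate(5000, choose_aa("W", pol))
  expect_false("W" %in% draws2)
  expect_gt(chisq.test(table(factor(draws2, levels = c("F", "Y", "L"))),
                       p = c(2, 1, 1) / 4)$p.value, 0.001)
})

test_that("generate_mutations yields pairwise-distinct sets or reports the achievable maximum", {
  cx <- make_toy_complex(5, 5, "two_strands", interface_gap = 5, seed = 4)
  cx$mutable <- data.frame(chain = "A", pos = 2L)
  # exhaustive: 19 possible single substitutions
  set.seed(5)
  all19 <- generate_mutations(cx, chooser_policy(), 19)
  keys <- vapply(all19, evobinder:::mutation_set_key, character(1))
  expect_equal(length(unique(keys)), 19)
  expect_false(any(grepl(cx$residues$aa[cx$residues$chain == "A" & cx$residues$pos == 2],
                         substr(keys, 6, 6), fixed = TRUE)))
  # pigeonhole: a 3-member group containing the current residue gives 2 sets
  cur <- binder_sequence(cx)[["A:2"]]
  grp <- c(cur, setdiff(AA20, cur)[1:2])
  pol <- chooser_policy(aa_scheme = "grouped", groups = list(g = grp),
                        active_group = "g")
  set.seed(6)
  expect_error(generate_mutations(cx, pol, 3), "at most 2")
  # multi-site: distinct sets with distinct positions inside each set
  cx$mutable <- data.frame(chain = "A", pos = 1:5)
  pol2 <- chooser_policy(sites_per_mutant = 2)
  set.seed(8)
  sets <- generate_mutations(cx, pol2, 8)
  expect_equal(length(sets), 8)
  expect_equal(anyDuplicated(vapply(sets, evobinder:::mutation_set_key, character(1))), 0L)
  for (ms in sets) {
    expect_equal(length(ms), 2)
    expect_false(ms[[1]]$pos == ms[[2]]$pos)
  }
})

test_that("equal seeds reproduce chooser outputs exactly", {
  cx <- make_toy_complex(8, 8, "two_strands", interface_gap = 5, seed = 4)
  pol <- chooser_policy()
  set.seed(42); a <- generate_mutations(cx, pol, 5)
  set.seed(42); b <- generate_mutations(cx, pol, 5)
  expect_identical(vapply(a, evobinder:::mutation_set_key, character(1)),
                   vapply(b, evobinder:::mutation_set_key, character(1)))
})
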