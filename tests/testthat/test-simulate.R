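test_that("composition estimation gives ML relative frequencies", {
  p <- estimate_composition(seq_set("s", c(a = "AACG")))
  expect_equal(unname(p$probs[1, ]), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(p$lengths), 4L)

  p2 <- estimate_composition(seq_set("s", c(a = "TTTT", b = "ACGT")))
  expect_equal(unname(p2$probs[1, ]), c(0, 0, 0, 1))
  expect_equal(rownames(p2$probs), c("a", "b"))

  # pseudocount keeps every base reachable
  p3 <- estimate_composition(seq_set("s", c(a = "TTTT")), pseudocount = 1)
  expect_true(all(p3$probs > 0))
  expect_equal(sum(p3$probs[1, ]), 1)
})

test_that("sequence generation follows the base probabilities", {
  set.seed(1)
  expect_equal(generate_sequence(c(1, 0, 0, 0), 10), "AAAAAAAAAA")

  set.seed(2)
  s <- generate_sequence(rep(0.25, 4), 1e5)
  freqs <- count_words(s, dna_alphabet()) / 1e5
  expect_true(all(abs(freqs - 0.25) < 0.01))

  set.seed(3); s1 <- generate_sequence(rep(0.25, 4), 50)
  set.seed(3); s2 <- generate_sequence(rep(0.25, 4), 50)
  expect_identical(s1, s2)

  expect_error(generate_sequence(rep(0.25, 4), 0), "positive")
  expect_error(generate_sequence(c(0.5, 0.5), 5), "alphabet")
})

test_that("generated sets scale lengths by the factor and are reproducible", {
  prof <- composition_profile("p", rbind(c(0.4, 0.3, 0.2, 0.1),
                                         c(0.1, 0.2, 0.3, 0.4)),
                              lengths = c(100, 57))
  g1 <- generate_seq_set(prof, factor = 1, seed = 5)
  expect_equal(unname(nchar(g1$sequences)), c(100L, 57L))
  g100 <- generate_seq_set(prof, factor = 100, seed = 5)
  expect_equal(unname(nchar(g100$sequences)), c(10000L, 5700L))
  g200 <- generate_seq_set(prof, factor = 200, seed = 5)
  expect_equal(unname(nchar(g200$sequences)), c(20000L, 11400L))

  # byte-identical FASTA across runs with the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_seq_set(generate_seq_set(prof, factor = 2, seed = 9), f1)
  write_seq_set(generate_seq_set(prof, factor = 2, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # different replicate index -> different stream
  expect_false(identical(generate_seq_set(prof, seed = 9, replicate = 1)$sequences,
                         generate_seq_set(prof, seed = 9, replicate = 2)$sequences))
})

test_that("collections contain m replicate sets with suffixed ids", {
  prof <- synthetic_profile(c(0.4, 0.3, 0.2, 0.1), n_seq = 2,
                            base_length = 50, set_id = "proto")
  coll <- generate_collection(prof, m = 20, factor = 1, seed = 4)
  expect_equal(length(coll$sets), 20L)
  expect_equal(coll$sets[[3]]$set_id, "proto_r3")
  expect_equal(generate_collection(prof, m = 1, factor = 1, seed = 4)$sets[[1]]$set_id,
               "proto_r1")
  coll2 <- generate_collection(prof, m = 20, factor = 1, seed = 4)
  expect_identical(coll, coll2)
  # substreams: set r is the same whether or not other sets were generated
  expect_identical(coll$sets[[7]]$sequences,
                   generate_seq_set(prof, factor = 1, seed = 4,
                                    replicate = 7)$sequences)
})

test_that("composition of long generated sets converges to the prototype", {
  prof <- synthetic_profile(c(0.35, 0.3, 0.2, 0.15), n_seq = 3,
                            base_length = 200, set_id = "p")
  g <- generate_seq_set(prof, factor = 1000, seed = 8)
  est <- estimate_composition(g)
  expect_lt(max(abs(est$probs - prof$probs)), 0.01)
})

test_that("the convergence diagnostic sees TV distance shrink with the factor", {
  prof <- synthetic_profile(c(0.4, 0.3, 0.2, 0.1), n_seq = 4,
                            base_length = 500, set_id = "p")
  rep_ <- convergence_diagnostic(prof, factors = c(1, 10, 100), reps = 10,
                                 seed = 21)
  expect_true(all(rep_$detail$tv >= 0 & rep_$detail$tv <= 1))
  expect_true(all(diff(rep_$summary$median_tv) < 0))

  # degenerate composition: TV identically zero
  dg <- composition_profile("d", rbind(c(1, 0, 0, 0)), lengths = 50)
  rep0 <- convergence_diagnostic(dg, factors = c(1, 10), reps = 3, seed = 1)
  expect_true(all(rep0$detail$tv == 0))

  # different seeds give different generated data (no stream leakage)
  a <- generate_seq_set(prof, factor = 1, seed = 1)
  b <- generate_seq_set(prof, factor = 1, seed = 2)
  expect_false(identical(a$sequences, b$sequences))
})

test_that("sliding windows report local composition", {
  tab <- sliding_window_composition("AAAACCCC", window = 4, step = 4)
  expect_equal(nrow(tab), 2L)
  expect_equal(unname(unlist(tab[1, c("A", "C", "G", "T")])), c(1, 0, 0, 0))
  expect_equal(unname(unlist(tab[2, c("A", "C", "G", "T")])), c(0, 1, 0, 0))

  # window = length reproduces the whole-sequence composition
  s <- "ACGTACGGTT"
  tab1 <- sliding_window_composition(s, window = nchar(s))
  prof <- estimate_composition(seq_set("x", c(a = s)))
  expect_equal(unname(unlist(tab1[1, c("A", "C", "G", "T")])),
               unname(prof$probs[1, ]))

  expect_equal(nrow(sliding_window_composition("ACGT", window = 2, step = 1)), 3L)
  expect_error(sliding_window_composition("ACG", window = 5), "exceeds")
})
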