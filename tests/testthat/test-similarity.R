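test_that("forests mirror the structure and refuse pseudoknots", {
  f4 <- structure_to_forest(parse_dotbracket("....", "AAAA"))
  expect_equal(f4$kind, rep(0L, 4))
  expect_equal(f4$parent, rep(0L, 4))
  fh <- structure_to_forest(parse_dotbracket("(...)", "GAAAC"))
  expect_equal(fh$kind, c(1L, 0L, 0L, 0L))
  expect_equal(fh$parent, c(0L, 1L, 1L, 1L))
  fn <- structure_to_forest(parse_dotbracket("((...))", "GGAAACC"))
  expect_equal(fn$kind, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(fn$parent, c(0L, 1L, 2L, 2L, 2L))
  pk <- parse_dotbracket("((..[[..))..]]", "GGAAGGAACCAACC")
  expect_error(structure_to_forest(pk), "pseudoknot")
})

test_that("local alignment scores match counting and are symmetric", {
  s <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  expect_equal(align_local(s, s), 44) # 4 P * 10 + 4 B * 1
  empty <- parse_dotbracket("", "")
  expect_equal(align_local(s, empty), 0)
  set.seed(401)
  for (i in 1:10) {
    a <- random_structure(sample(10:30, 1))
    b <- random_structure(sample(10:30, 1))
    expect_equal(align_local(a, b), align_local(b, a))
  }
  # no alignment beats identity under the default scoring
  for (i in 1:10) {
    a <- random_structure(sample(10:30, 1))
    b <- random_structure(sample(10:30, 1))
    expect_lte(align_local(a, b),
               max(align_local(a, a), align_local(b, b)))
  }
})

test_that("dinucleotide shuffling preserves counts and endpoints", {
  sqs <- c("GCAUGCAUGC", "AAAA", "GGGCCCAAAUUU", "ACGUACGUACGUAA")
  set.seed(402)
  for (sq in sqs) {
    sh <- dinucleotide_shuffle(sq)
    expect_equal(nchar(sh), nchar(sq))
    expect_equal(dinucleotide_counts(sh), dinucleotide_counts(sq))
    expect_equal(substr(sh, 1, 1), substr(sq, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)),
                 substr(sq, nchar(sq), nchar(sq)))
  }
  expect_equal(withr::with_seed(1, dinucleotide_shuffle("AAAA")), "AAAA")
  expect_error(dinucleotide_shuffle("AG"), "length")
  expect_error(dinucleotide_shuffle("ACGTX"), "A, C, G, U")
})

test_that("shuffle support equals the brute-force Eulerian arrangement set", {
  for (sq in c("GCAUGC", "AGGAUG", "ACACAC")) {
    want <- sort(oracle_shuffle_set(sq))
    got <- sort(unique(vapply(1:400, function(s) {
      withr::with_seed(s, dinucleotide_shuffle(sq))
    }, character(1))))
    expect_equal(got, want)
  }
})

test_that("baseline folding maximizes pairs (enumeration oracle)", {
  expect_equal(nrow(fold_baseline("AAAA")$pairs), 0)
  expect_equal(nrow(fold_baseline("GGGAAACCC")$pairs), 3)
  set.seed(403)
  for (i in 1:30) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1), TRUE),
                collapse = "")
    expect_equal(nrow(fold_baseline(sq)$pairs), oracle_max_pairs(sq))
  }
  # deterministic traceback
  expect_identical(format_dotbracket(fold_baseline("GCGCGCAAAGCGC")),
                   format_dotbracket(fold_baseline("GCGCGCAAAGCGC")))
})

test_that("Z-scores behave at the edges and reproduce under seeding", {
  toy <- toy_fixtures()
  r1 <- zscore_screen(toy$query, toy$planted, n_shuffles = 100, seed = 5)
  r2 <- zscore_screen(toy$query, toy$planted, n_shuffles = 100, seed = 5)
  expect_equal(r1$z, r2$z)
  expect_equal(r1$z, (r1$score - r1$null_mean) / r1$null_sd)
  # zero-variance null: Z undefined and flagged
  const <- parse_dotbracket("....", "AAAA")
  expect_warning(r0 <- zscore_screen(const, const, n_shuffles = 20, seed = 1),
                 "zero variance")
  expect_true(is.na(r0$z))
  expect_false(r0$significant)
})

test_that("Z is invariant under affine rescaling of the scoring weights", {
  toy <- toy_fixtures()
  base <- zscore_screen(toy$query, toy$planted, n_shuffles = 150, seed = 6)
  scaled <- zscore_screen(toy$query, toy$planted, n_shuffles = 150, seed = 6,
                          scoring = list(pair_match = 30, base_match = 3,
                                         gap = -15))
  expect_equal(base$z, scaled$z)
})

test_that("screen_matrix evaluates the cross product and summarises bins", {
  toy <- toy_fixtures()
  helices <- tibble::tibble(id = c("q1", "q2"), nd = c(0.05, 0.55),
                            structure = list(toy$query, toy$control))
  parts <- tibble::tibble(id = c("planted", "control"),
                          structure = list(toy$planted, toy$control))
  out <- screen_matrix(helices, parts, n_shuffles = 100, seed = 7)
  expect_equal(nrow(out$results), 4)
  expect_true(out$results$significant[out$results$helix == "q1" &
                                        out$results$part == "planted"])
  expect_equal(sum(out$by_bin$n), 4)
  empty <- screen_matrix(helices[0, ], parts, n_shuffles = 10)
  expect_equal(nrow(empty$results), 0)
})
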