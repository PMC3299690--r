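test_that("dot-bracket parsing recovers pair maps and flags errors", {
  s <- parse_dotbracket("((..))", "GGAACC")
  expect_equal(s$pairs, cbind(c(1, 2), c(6, 5)), ignore_attr = TRUE)
  expect_equal(nrow(parse_dotbracket("......", "AAAAAA")$pairs), 0)
  s3 <- parse_dotbracket("((((....))))", "GGGGAAAACCCC")
  expect_equal(nrow(s3$pairs), 4)
  expect_true(any(s3$pairs[, 1] == 4 & s3$pairs[, 2] == 9))
  expect_error(parse_dotbracket("((.)", "GGAC"), "unbalanced")
  expect_error(parse_dotbracket("(..))", "GGACC"), "position")
  expect_error(parse_dotbracket("...", "AAAA"), "lengths differ")
  pk <- parse_dotbracket("((..[[..))..]]", "GGAAGGAACCAACC")
  expect_true(pk$pseudoknotted)
  expect_equal(nrow(pk$pairs), 2)
  expect_equal(nrow(pk$pk_pairs), 2)
})

test_that("decomposition reproduces hand-worked segmentations", {
  d1 <- decompose_structure(parse_dotbracket("((((....))))", "GGGGAAAACCCC"))
  expect_equal(d1$kind, c("S", "H"))
  expect_equal(d1$length, c(4, 4))

  d2 <- decompose_structure(
    parse_dotbracket("((..((...))..))", "NNNNNNNNNNNNNNN"))
  expect_equal(d2$kind, c("S", "B", "S", "H", "B"))
  expect_equal(d2$length, c(2, 2, 2, 3, 2))
  expect_equal(unique(d2$region), "R1") # one helix region

  d3 <- decompose_structure(parse_dotbracket(".((...)).", "ANNNNNNNA"))
  expect_equal(d3$kind, c("U", "S", "H", "U"))
  expect_equal(d3$length, c(1, 2, 3, 1))
})

test_that("decomposition partitions every position (S strands counted twice)", {
  set.seed(201)
  for (i in 1:25) {
    s <- random_structure(sample(15:60, 1))
    d <- decompose_structure(s)
    covered <- sum(d$length * ifelse(d$kind == "S", 2, 1))
    expect_equal(covered, nchar(s$sequence))
  }
})

test_that("multiloops delimit helix regions", {
  # two hairpin helices inside an enclosing stem -> 3 regions
  s <- parse_dotbracket("((..((...))..((...))..))",
                        strrep("N", 24))
  d <- decompose_structure(s)
  expect_equal(length(unique(d$region[d$kind == "S"])), 3)
  # multiloop spacers are U, not B
  expect_true(all(d$kind[d$start %in% c(3, 12, 21)] == "U"))
})

test_that("template decomposition of an aligned copy matches the unaligned one", {
  plain <- parse_dotbracket(".((...)).", "ANNNNNNNA")
  d_plain <- decompose_structure(plain)
  # gapped copy: gap columns (sequence '-') inside U and H segments
  gapped <- parse_dotbracket("..((....))..", "A-NNN-NNNN-A")
  tmpl <- homology_template(
    c("R1.U1", "R1.S1", "R1.H1", "R1.S1'", "R1.U2"),
    col_start = c(1, 3, 5, 9, 11),
    col_end = c(2, 4, 8, 10, 12)
  )
  d_tmpl <- decompose_structure(gapped, regions = tmpl)
  # same U/S/H/U lengths as the unaligned structure (S' mirrors S)
  expect_equal(d_tmpl$length, c(d_plain$length, 2)[c(1, 2, 3, 5, 4)])
  expect_equal(d_plain$length, c(1, 2, 3, 1))
})

test_that("helix-map TSV round-trips and rejects malformed files", {
  sim <- simulate_accretion(n_taxa = 5, n_helices = 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_structural_alignment(sim$lengths, f)
  loaded <- load_structural_alignment(f)
  expect_equal(loaded$lengths, sim$lengths)
  expect_equal(nrow(loaded$template), 12) # 4 helices x (S1, H1, S1')
  expect_length(loaded$structures, 5)
  # synthesized structures decompose back to the recorded stem lengths
  d <- decompose_structure(loaded$structures[[1]])
  stem <- d$length[d$kind == "S"]
  expect_equal(sort(stem),
               sort(unlist(sim$lengths[1, grepl("\\.S1$",
                                                names(sim$lengths))])),
               ignore_attr = TRUE)

  writeLines(c("taxon\th1.S1\th1.S1'", "t1\t3"), f)
  expect_error(load_structural_alignment(f), "ragged")
  writeLines(c("organism\th1.S1", "t1\t3"), f)
  expect_error(load_structural_alignment(f), "taxon")
  writeLines(c("taxon\tbadslot", "t1\t3"), f)
  expect_error(load_structural_alignment(f), "slot")
})

test_that("NEXUS export round-trips, with one ancestral declaration", {
  m <- polarize(toy_fixtures()$matrix)
  f <- withr::local_tempfile(fileext = ".nex")
  write_character_matrix(m, f)
  txt <- readLines(f)
  expect_length(grep("ANCSTATES", txt), 1)
  expect_length(grep("DEFTYPE=ord", txt), 1)
  m2 <- read_character_matrix(f)
  expect_identical(m2$states, m$states)
  expect_identical(m2$ancestral, m$ancestral)
  expect_true(m2$ordered)

  big <- simulate_accretion(n_taxa = 20, n_helices = 10, seed = 3)
  mb <- build_matrix(big$lengths)
  write_character_matrix(mb, f)
  expect_equal(length(read_character_matrix(f)$taxa), 20)
})
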