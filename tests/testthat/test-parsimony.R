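test_that("tree length matches hand-worked ordered-cost cases", {
  m3 <- character_matrix(matrix(c("0", "2", "5"), 3, 1,
                                dimnames = list(c("A", "B", "C"), "c1")))
  expect_equal(tree_length(ape::read.tree(text = "(A,B,C);"), m3), 5)
  m4 <- character_matrix(matrix(c("0", "0", "3", "3"), 4, 1,
                                dimnames = list(LETTERS[1:4], "c1")))
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(tree_length(t4, m4), 3)
  mc <- character_matrix(matrix("5", 4, 2, dimnames = list(LETTERS[1:4],
                                                           c("c1", "c2"))))
  expect_equal(tree_length(t4, mc), 0)
  expect_error(tree_length(t4, m3), "missing|without data")
})

test_that("Sankoff scoring agrees with brute-force assignment enumeration", {
  set.seed(101)
  for (i in 1:40) {
    ntip <- sample(4:6, 1)
    ns <- sample(3:6, 1)
    states <- sample(0:(ns - 1), ntip, replace = TRUE)
    phy <- ape::rtree(ntip)
    phy$edge.length <- NULL
    phy$tip.label <- paste0("t", seq_len(ntip))
    m <- character_matrix(matrix(as.character(states), ntip, 1,
                                 dimnames = list(phy$tip.label, "c1")))
    expect_equal(tree_length(phy, m),
                 oracle_tree_length(phy, states, ns))
  }
})

test_that("tree length is invariant to root position", {
  set.seed(102)
  m <- random_digit_matrix(7, 5)
  phy <- ape::rtree(7)
  phy$edge.length <- NULL
  phy$tip.label <- m$taxa
  un <- ape::unroot(phy)
  lens <- vapply(2:6, function(k) {
    tree_length(ape::root(un, outgroup = m$taxa[k], resolve.root = TRUE), m)
  }, numeric(1))
  expect_true(all(lens == tree_length(phy, m)))
})

test_that("scoring agrees with phangorn's Sankoff on digit matrices", {
  skip_if_not_installed("phangorn")
  set.seed(103)
  for (i in 1:5) {
    m <- random_digit_matrix(6, 8, max_state = 5)
    phy <- ape::rtree(6)
    phy$edge.length <- NULL
    phy$tip.label <- m$taxa
    lv <- as.character(0:5)
    dat <- phangorn::phyDat(m$states, type = "USER", levels = lv)
    cost <- abs(outer(0:5, 0:5, "-"))
    dimnames(cost) <- list(lv, lv)
    ph <- phangorn::sankoff(phy, dat, cost = cost)
    # restrict our scorer to the same 6-state alphabet
    m6 <- character_matrix(m$states, alphabet = lv)
    expect_equal(tree_length(phy, m6), unname(ph))
  }
})

test_that("per-character bounds give range and star-tree cost", {
  m <- character_matrix(matrix(c("0", "2", "5",
                                 "0", "0", "4",
                                 "0", "4", "8"), 3, 3,
                               dimnames = list(letters[1:3], NULL)))
  b <- per_character_bounds(m)
  expect_equal(b$min_steps, c(5, 4, 8))
  expect_equal(b$max_steps, c(5, 4, 8))
  m5 <- character_matrix(matrix(c("0", "4", "4", "4", "8"), 5, 1))
  b5 <- per_character_bounds(m5)
  expect_equal(b5$min_steps, 8)
  expect_equal(b5$max_steps, 8)
  const <- character_matrix(matrix("3", 4, 1))
  expect_equal(unlist(per_character_bounds(const)[1, 2:3]), c(0, 0),
               ignore_attr = TRUE)
})

test_that("fit statistics satisfy their identities", {
  # perfectly fitting data: one binary character on a matching tree
  m <- character_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
                               dimnames = list(LETTERS[1:4], "c1")))
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  fs <- fit_stats(t4, m, n_random_trees = 0)
  expect_equal(fs$ci, 1)
  expect_equal(fs$hi, 0)
  # L within [sum_min, sum_max], CI/RI in [0,1], HI = 1 - CI on random data
  set.seed(104)
  for (i in 1:10) {
    mm <- random_digit_matrix(6, 6)
    phy <- ape::rtree(6)
    phy$edge.length <- NULL
    phy$tip.label <- mm$taxa
    f <- fit_stats(phy, mm, n_random_trees = 0)
    expect_gte(f$length, f$sum_min)
    expect_lte(f$length, f$sum_max)
    expect_true(f$ci >= 0 && f$ci <= 1)
    expect_true(is.na(f$ri) || (f$ri >= 0 && f$ri <= 1))
    expect_equal(f$hi, 1 - f$ci)
  }
  # indices stay bounded when the tree covers a subset of the matrix taxa
  mm8 <- random_digit_matrix(8, 5)
  sub <- ape::rtree(5)
  sub$edge.length <- NULL
  sub$tip.label <- mm8$taxa[1:5]
  fsub <- fit_stats(sub, mm8, n_random_trees = 0)
  expect_gte(fsub$length, fsub$sum_min)
  expect_true(fsub$ci <= 1)
  # g1 ~ 0 for a symmetric length distribution is exercised via a constant
  # matrix (all random trees same length -> skewness NaN/0 handled upstream);
  # here check g1 is reproducible and finite on signal data
  mm <- random_digit_matrix(8, 6)
  phy <- heuristic_search(mm)[[1]]
  f1 <- fit_stats(phy, mm, n_random_trees = 150, seed = 9)
  f2 <- fit_stats(phy, mm, n_random_trees = 150, seed = 9)
  expect_equal(f1$g1, f2$g1)
  expect_true(is.finite(f1$g1))
})

test_that("heuristic search finds the exhaustive optimum on small matrices", {
  set.seed(105)
  for (i in 1:12) {
    m <- random_digit_matrix(6, 5)
    res <- heuristic_search(m)
    expect_equal(attr(res, "best_length"), exhaustive_best_length(m))
  }
  # single binary character: length equals its min_steps
  mb <- character_matrix(matrix(c("0", "0", "1", "1", "1"), 5, 1,
                                dimnames = list(paste0("t", 1:5), "c1")))
  expect_equal(attr(heuristic_search(mb), "best_length"), 1)
  # duplicating a taxon leaves the best length unchanged
  m <- random_digit_matrix(5, 4)
  st2 <- rbind(m$states, dup = m$states[1, ])
  rownames(st2) <- c(m$taxa, "dup")
  m2 <- character_matrix(st2)
  expect_equal(attr(heuristic_search(m2), "best_length"),
               attr(heuristic_search(m), "best_length"))
})

test_that("search is reproducible and warns below 4 taxa", {
  m <- random_digit_matrix(8, 5)
  r1 <- heuristic_search(m, addition = "random", n_starts = 3, seed = 7)
  r2 <- heuristic_search(m, addition = "random", n_starts = 3, seed = 7)
  expect_equal(attr(r1, "best_length"), attr(r2, "best_length"))
  expect_equal(ape::write.tree(r1[[1]]), ape::write.tree(r2[[1]]))
  m3 <- random_digit_matrix(3, 4)
  expect_warning(heuristic_search(m3), "fewer than 4")
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(rf_distance(strict_consensus(list(t1)), t1), 0)
  t2 <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  cons <- strict_consensus(list(t1, t2))
  # only the (D,E) clade survives
  bp <- riboclock:::nontrivial_bipartitions(cons)
  expect_equal(length(bp), 1)
  expect_true(any(vapply(bp, function(b) setequal(b, c("D", "E")),
                         logical(1))))
  t3 <- ape::read.tree(text = "((A,D),(C,(B,E)));")
  star <- strict_consensus(list(t1, t3))
  expect_equal(length(riboclock:::nontrivial_bipartitions(star)), 0)
  expect_error(strict_consensus(list(t1, ape::read.tree(text = "((A,B),C);"))),
               "leaf")
})

test_that("RF distance counts one-sided bipartitions and matches phangorn", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  t5 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(rf_distance(star, t5), 2)
  skip_if_not_installed("phangorn")
  set.seed(106)
  for (i in 1:10) {
    a <- ape::rtree(7)
    b <- ape::rtree(7)
    expect_equal(rf_distance(a, b),
                 phangorn::RF.dist(ape::unroot(a), ape::unroot(b)))
  }
})

test_that("bootstrap supports are reproducible percentages", {
  sim <- simulate_accretion(n_taxa = 8, n_helices = 6, seed = 6)
  m <- build_matrix(sim$lengths, orientation = "substructure_rows")
  b1 <- bootstrap_support(m, reps = 25, seed = 3)
  b2 <- bootstrap_support(m, reps = 25, seed = 3)
  expect_equal(ape::write.tree(b1), ape::write.tree(b2))
  expect_true(all(b1$node.label >= 0 & b1$node.label <= 100))
  # reps = 1: supports only 0 or 100
  b3 <- bootstrap_support(m, reps = 1, seed = 4)
  expect_true(all(b3$node.label %in% c(0, 100)))
})

test_that("ancestor rooting matches brute force over attachment branches", {
  set.seed(107)
  for (i in 1:8) {
    m <- polarize(random_digit_matrix(5, 4))
    res <- heuristic_search(m)
    un <- res[[1]]
    rooted <- root_with_ancestor(un, m)
    # brute force: score ancestor attachment on every branch
    anc_lab <- "ZANC"
    st2 <- rbind(m$states, m$ancestral)
    rownames(st2) <- c(m$taxa, anc_lab)
    m2 <- character_matrix(st2)
    tr <- ape::compute.brlen(un, 1)
    cand <- vapply(seq_len(nrow(tr$edge)), function(k) {
      tr2 <- suppressWarnings(
        phytools::bind.tip(tr, anc_lab, where = tr$edge[k, 2],
                           position = 0.5))
      tree_length(tr2, m2)
    }, numeric(1))
    expect_equal(attr(rooted, "root_length"), min(cand))
  }
  # ancestor identical to one leaf roots adjacent to that leaf
  m <- character_matrix(matrix(c("0", "1", "4", "5"), 4, 1,
                               dimnames = list(LETTERS[1:4], "c1")),
                        ancestral = "5")
  r <- root_with_ancestor(ape::read.tree(text = "(A,B,(C,D));"), m)
  nd <- node_distance(r)
  expect_equal(nd$nd[nd$id == "D"], 0)
  # all-constant matrix: every branch ties
  mc <- character_matrix(matrix("3", 4, 2,
                                dimnames = list(LETTERS[1:4], NULL)),
                         ancestral = c("3", "3"))
  expect_message(root_with_ancestor(ape::read.tree(text = "(A,B,(C,D));"),
                                    mc),
                 "ties")
})

test_that("ancestral reconstruction attains the tree length", {
  # constant character stays constant everywhere
  mc <- character_matrix(matrix("4", 4, 1,
                                dimnames = list(LETTERS[1:4], "c1")))
  t4 <- ape::read.tree(text = "((A,B),(C,D));")
  a <- ancestral_states(t4, mc)
  expect_true(all(a$states == "4"))
  # 3-leaf median
  m3 <- character_matrix(matrix(c("0", "2", "5"), 3, 1,
                                dimnames = list(c("A", "B", "C"), "c1")))
  t3 <- ape::read.tree(text = "((A,B),C);")
  a3 <- ancestral_states(t3, m3)
  expect_equal(a3$states[4, 1], "2") # root state is the median
  # cost equality on random fixtures
  set.seed(108)
  for (i in 1:8) {
    m <- random_digit_matrix(6, 5)
    phy <- ape::rtree(6)
    phy$edge.length <- NULL
    phy$tip.label <- m$taxa
    a <- ancestral_states(phy, m)
    expect_equal(a$cost, tree_length(phy, m))
  }
})
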