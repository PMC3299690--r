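test_that("node distance counts internal nodes and hits the 0/1 endpoints", {
  t <- ape::read.tree(text = "(((A,B),C),D);")
  nd <- node_distance(t)
  expect_equal(nd$nd[match(c("D", "C", "A", "B"), nd$id)],
               c(0, 0.5, 1, 1))
  # deepest leaf is always 1; a leaf at the root split is always 0
  set.seed(301)
  for (i in 1:10) {
    tr <- riboclock:::yule_tree(sample(5:25, 1))
    nd <- node_distance(tr)
    expect_equal(max(nd$nd), 1)
    expect_true(all(nd$nd >= 0))
  }
  for (n in c(5, 9, 14)) {
    nd <- node_distance(riboclock:::caterpillar_tree(n))
    expect_equal(nd$nd[nd$id == paste0("t", n)], 0) # basal leaf
    expect_equal(max(nd$nd), 1)
  }
  # equidistant leaves: degenerate warning, all zero
  bal <- ape::read.tree(text = "(A,B,C,D);")
  expect_warning(ndb <- node_distance(bal), "equidistant")
  expect_true(all(ndb$nd == 0))
})

test_that("node distance order survives constant-depth extension", {
  t <- ape::read.tree(text = "(((A,B),C),D);")
  base <- node_distance(t)
  # replace every leaf with a cherry (constant-depth subtree)
  t2 <- t
  for (lab in t$tip.label) {
    t2 <- suppressWarnings(
      phytools::bind.tip(ape::compute.brlen(t2, 1), paste0(lab, "x"),
                         where = which(t2$tip.label == lab), position = 0))
  }
  nd2 <- node_distance(t2)
  ord1 <- rank(base$nd[match(c("A", "B", "C", "D"), base$id)])
  ord2 <- rank(nd2$nd[match(c("A", "B", "C", "D"), nd2$id)])
  expect_equal(ord1, ord2)
})

test_that("imbalance statistics count depths and cherries", {
  expect_equal(
    as.list(imbalance_stats(ape::read.tree(text = "((A,B),(C,D));"))),
    list(n_bar = 2, cherries = 2L))
  cat6 <- riboclock:::caterpillar_tree(6)
  expect_equal(imbalance_stats(cat6)$cherries, 1L)
  two <- ape::read.tree(text = "(A,B);")
  expect_equal(as.list(imbalance_stats(two)), list(n_bar = 1, cherries = 1L))
})

test_that("Yule nulls match the n/3 cherry expectation and reject pectinate trees", {
  ne <- null_tree_ensemble(30, "yule", reps = 600, seed = 11)
  expect_lt(abs(mean(ne$stats$cherries) - 10), 0.35) # 3 MC sd approx
  # caterpillar strongly rejected
  obs <- riboclock:::caterpillar_tree(20)
  ne2 <- null_tree_ensemble(20, "yule", reps = 2000, seed = 12,
                            observed = obs)
  expect_lt(ne2$p_cherries, 0.01)
  expect_lt(ne2$p_n_bar, 0.01)
  # uniform and Yule cherry means differ
  nu <- null_tree_ensemble(30, "uniform_random", reps = 600, seed = 11)
  expect_gt(abs(mean(nu$stats$cherries) - mean(ne$stats$cherries)), 1)
  # self-consistency: a Yule draw is inside its own 99% envelope
  tr <- withr::with_seed(13, riboclock:::yule_tree(30))
  ne3 <- null_tree_ensemble(30, "yule", reps = 600, seed = 14, observed = tr)
  expect_gt(ne3$p_cherries, 0.01)
})

test_that("timelines date bridges by rule and preserve annotations", {
  chron <- tibble::tibble(id = c("h44", "H71", "h24"), nd = c(0, 0.4, 0.2))
  ann <- tibble::tibble(id = c("B5", "C1"), class = c("bridge", "contact"),
                        acceptor = c("h44", NA), donor = c("H71", NA),
                        helix = c(NA, "h24"))
  tl <- assemble_timeline(chron, ann)
  expect_equal(tl$nd[tl$id == "B5"], 0)
  tl2 <- assemble_timeline(chron, ann, bridge_rule = "max")
  expect_equal(tl2$nd[tl2$id == "B5"], 0.4)
  expect_setequal(tl$id, ann$id) # permutation of inputs
  expect_true(!is.unsorted(tl$nd))
  expect_equal(nrow(assemble_timeline(chron, ann[0, ])), 0)
  bad <- ann
  bad$helix[2] <- "h999"
  expect_error(assemble_timeline(chron, bad), "h999")
})

test_that("protein ages follow the youngest-domain rule", {
  l2 <- tibble::tibble(domain = c("b.40.4", "b.34.5"),
                       nd_p = c(0.037, 0.347))
  expect_equal(protein_age(l2)$nd_p, 0.347)
  one <- tibble::tibble(domain = "d", nd_p = 0.25)
  expect_equal(protein_age(one)$nd_p, 0.25)
  res <- protein_age(tibble::tibble(domain = c("x", "y"), nd_p = c(0.1, 0.2)),
                     combination_age = 0.5)
  expect_equal(res$nd_p, 0.2)
  expect_true(res$combination_postdates)
  expect_error(protein_age(tibble::tibble(domain = character(),
                                          nd_p = numeric())),
               "empty")
})

test_that("coevolution regression reproduces closed-form OLS", {
  line <- tibble::tibble(nd = c(0, 0.1, 0.2, 0.3),
                         nd_p = 2 * c(0, 0.1, 0.2, 0.3) * 0.3)
  fit <- interpolate_protein_age(line, nd_p_max = Inf)
  expect_equal(fit$slope, 0.6)
  expect_equal(fit$r_squared, 1)
  # hand case with zero explained variance
  tri <- tibble::tibble(nd = c(0, 1, 2), nd_p = c(0, 1, 0))
  fit0 <- interpolate_protein_age(tri, nd_max = Inf, nd_p_max = Inf)
  expect_equal(fit0$r_squared, 0)
  expect_equal(fit0$slope, 0)
  # query maps through the fitted line, both directions
  fitq <- interpolate_protein_age(line, query = 0.25, nd_p_max = Inf)
  expect_equal(fitq$predicted, 0.15)
  fitr <- interpolate_protein_age(line, query = 0.15,
                                  direction = "nd_p_to_nd", nd_p_max = Inf)
  expect_equal(fitr$predicted, 0.25)
  expect_error(interpolate_protein_age(line[1:2, ], nd_p_max = Inf), ">= 3")
  flat <- tibble::tibble(nd = rep(0.1, 4), nd_p = 1:4 / 10)
  expect_error(interpolate_protein_age(flat, nd_p_max = Inf), "variance")
})

test_that("heat-map colours bin at 0.01 and honour rescaling", {
  x <- tibble::tibble(id = c("a", "b", "c"), nd = c(0, 0.504, 1))
  hc <- heatmap_colors(x)
  pal <- grDevices::colorRampPalette(c("blue", "red"))(101)
  expect_equal(hc$hex, pal[c(1, 51, 101)])
  expect_equal(hc$bin, c(0, 0.5, 1))
  y <- tibble::tibble(id = c("a", "b"), nd_p = c(0.018, 0.534))
  hy <- heatmap_colors(y, rescale = TRUE)
  expect_equal(hy$bin, c(0, 1)) # endpoints map to the scale ends
  expect_error(heatmap_colors(tibble::tibble(id = "a", nd = 1.2)),
               "outside")
})
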