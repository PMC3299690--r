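#' Parsimony tree length under ordered (Wagner) state costs
#'
#' The minimum number of steps needed to explain a character matrix on a
#' given topology, where a change between states i and j costs |i - j|
#' alphabet positions. Computed by Sankoff dynamic programming; for ordered
#' costs the per-node minimisation is a linear-time distance transform. The
#' length does not depend on where the tree is rooted.
#'
#' @param t A `phylo` tree whose tips are taxa of `m`.
#' @param m A [character_matrix()].
#' @param per_character Return the per-character step vector instead of the
#'   total.
#' @return Integer total steps (or named numeric vector).
#' @export
tree_length <- function(t, m, per_character = FALSE) {
  stopifnot(inherits(t, "phylo"), inherits(m, "character_matrix"))
  pieces <- phylo_to_edge(t)
  st <- tip_state_matrix(m, pieces$labels)
  pc <- sankoff_per_char_cpp(pieces$edge, pieces$ntip, st, length(m$alphabet))
  names(pc) <- m$characters
  if (per_character) pc else sum(pc)
}

#' Per-character step bounds for fit indices
#'
#' For an ordered character the minimum conceivable steps on any tree equal
#' the range of observed states; the maximum is the star-tree cost, i.e. the
#' smallest total distance from a single ancestral value (attained at the
#' median). These bounds feed the consistency and retention indices.
#'
#' @param m A [character_matrix()].
#' @return Tibble with `character`, `min_steps`, `max_steps`.
#' @export
per_character_bounds <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  bounds <- apply(m$states, 2, function(col) {
    v <- symbol_index(col[col != "?"], m$alphabet)
    if (!length(v)) return(c(0, 0))
    mn <- diff(range(v))
    star <- min(vapply(min(v):max(v), function(a) sum(abs(v - a)), numeric(1)))
    c(mn, star)
  })
  tibble::tibble(character = m$characters,
                 min_steps = unname(bounds[1, ]),
                 max_steps = unname(bounds[2, ]))
}

#' Tree fit statistics: length, CI, RI, HI and g1
#'
#' CI = sum(min_steps)/L, RI = (sum(max_steps) - L)/(sum(max_steps) -
#' sum(min_steps)), HI = 1 - CI. g1 is the small-sample-corrected skewness
#' (Sokal-Rohlf) of tree lengths over uniformly random topologies on the same
#' matrix: strongly negative g1 indicates concentrated phylogenetic signal.
#'
#' @param t A `phylo` tree.
#' @param m A [character_matrix()].
#' @param n_random_trees Random topologies for the g1 length distribution
#'   (0 skips g1).
#' @param seed Optional seed for the random-topology sample.
#' @return Object of class `parsimony_fit`.
#' @export
fit_stats <- function(t, m, n_random_trees = 1000, seed = NULL) {
  # indices are defined on the taxa the tree actually covers
  if (!setequal(t$tip.label, m$taxa)) {
    m <- character_matrix(m$states[t$tip.label, , drop = FALSE],
                          ordered = m$ordered, alphabet = m$alphabet,
                          ancestral = m$ancestral)
  }
  L <- tree_length(t, m)
  b <- per_character_bounds(m)
  smin <- sum(b$min_steps)
  smax <- sum(b$max_steps)
  ci <- if (L > 0) smin / L else 1
  ri <- if (smax > smin) (smax - L) / (smax - smin) else NA_real_
  g1 <- NA_real_
  lens <- NULL
  if (n_random_trees > 0) {
    st <- tip_state_matrix(m, m$taxa)
    ns <- length(m$alphabet)
    ntip <- length(m$taxa)
    draw <- function() {
      e <- random_topology_edge(ntip)
      score_edge_cpp(e, ntip, st, ns, rep(1, ncol(st)))
    }
    lens <- if (is.null(seed)) {
      replicate(n_random_trees, draw())
    } else {
      withr::with_seed(seed, replicate(n_random_trees, draw()))
    }
    g1 <- e1071::skewness(lens, type = 2)
  }
  structure(
    list(length = L, ci = ci, ri = ri, hi = 1 - ci, g1 = g1,
         sum_min = smin, sum_max = smax,
         n_random_trees = n_random_trees, random_lengths = lens),
    class = "parsimony_fit"
  )
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat("<parsimony_fit> L =", x$length,
      sprintf("CI = %.6f RI = %s HI = %.6f g1 = %s",
              x$ci, format(x$ri, digits = 6), x$hi,
              format(x$g1, digits = 6)), "\n")
  invisible(x)
}

#' @export
glance.parsimony_fit <- function(x, ...) {
  tibble::tibble(length = x$length, ci = x$ci, ri = x$ri, hi = x$hi,
                 g1 = x$g1, sum_min = x$sum_min, sum_max = x$sum_max)
}

#' @export
tidy.parsimony_fit <- function(x, ...) {
  tidyr::pivot_longer(glance(x), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' Heuristic maximum-parsimony search
#'
#' Builds a starting tree by stepwise addition (each taxon inserted at the
#' cheapest branch, ties broken toward the first branch in enumeration order)
#' and refines it by TBR branch swapping until no rearrangement shortens the
#' tree, accepting the first improvement found (deterministic given the
#' addition sequence). All distinct equally most-parsimonious topologies found
#' at convergence are returned, up to `max_trees`.
#'
#' @param m A [character_matrix()]; its rows are the operational taxa.
#' @param addition `"input_order"` (the simple addition sequence) or
#'   `"random"` (`n_starts` random addition sequences).
#' @param n_starts Random-addition replicates when `addition = "random"`.
#' @param seed Seed for random addition order.
#' @param max_trees Cap on retained equally parsimonious trees.
#' @return A list of `phylo` trees with attributes `length` (best steps) and
#'   `capped` (TRUE if the tie cap was hit).
#' @export
heuristic_search <- function(m, addition = c("input_order", "random"),
                             n_starts = 10, seed = NULL, max_trees = 1000) {
  stopifnot(inherits(m, "character_matrix"))
  addition <- match.arg(addition)
  ntip <- length(m$taxa)
  ns <- length(m$alphabet)
  if (ntip < 4) {
    warning("fewer than 4 taxa: returning the trivial topology",
            call. = FALSE)
    txt <- if (ntip == 3) "(t1,t2,t3);" else if (ntip == 2) "(t1,t2);" else "(t1);"
    phy <- ape::read.tree(text = txt)
    phy$tip.label <- m$taxa[seq_len(ntip)]
    len0 <- if (ntip >= 2) tree_length(phy, m) else 0
    return(structure(list(phy), best_length = len0, capped = FALSE))
  }
  orders <- if (addition == "input_order") {
    list(seq_len(ntip))
  } else {
    gen <- function() replicate(n_starts, sample.int(ntip), simplify = FALSE)
    if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  }
  w <- rep(1, length(m$characters))
  best_len <- Inf
  best <- list()
  best_keys <- character()
  for (ord in orders) {
    st <- tip_state_matrix(m, m$taxa[ord])
    start <- stepwise_addition_edge(st, ns, w)
    res <- tbr_search_cpp(start, ntip, st, ns, w, max_trees, 10000L)
    if (res$length < best_len - 1e-9) {
      best_len <- res$length
      best <- list()
      best_keys <- character()
    }
    if (res$length <= best_len + 1e-9) {
      for (e in res$trees) {
        phy <- edge_to_phylo(e, m$taxa[ord])
        key <- topology_key(phy)
        if (!key %in% best_keys) {
          best_keys <- c(best_keys, key)
          best[[length(best) + 1]] <- phy
        }
      }
    }
  }
  capped <- length(best) >= max_trees
  if (capped) {
    warning("tie cap reached: retained ", max_trees, " trees", call. = FALSE)
    best <- best[seq_len(max_trees)]
  }
  structure(best, best_length = best_len, capped = capped)
}

# stepwise addition on a 0-based state matrix whose rows are the addition
# order; ties broken to the first (lowest row index) edge
stepwise_addition_edge <- function(st, ns, w) {
  ntip <- nrow(st)
  edge <- .start_tree3(ntip)
  nxt <- ntip + 2L
  for (t in seq2(4L, ntip)) {
    best_k <- 1L
    best_len <- Inf
    for (k in seq_len(nrow(edge))) {
      cand <- .insert_tip(edge, k, t, nxt)
      len <- score_edge_cpp(cand, ntip, st, ns, w)
      if (len < best_len - 1e-9) {
        best_len <- len
        best_k <- k
      }
    }
    edge <- .insert_tip(edge, best_k, t, nxt)
    nxt <- nxt + 1L
  }
  edge
}

# canonical topology fingerprint: sorted non-trivial bipartitions by label
topology_key <- function(phy) {
  bp <- nontrivial_bipartitions(phy)
  paste(sort(vapply(bp, paste, character(1), collapse = ",")), collapse = "|")
}

# non-trivial bipartitions as sorted label vectors, normalized to the side
# not containing the alphabetically first label
nontrivial_bipartitions <- function(phy) {
  labs <- sort(phy$tip.label)
  parts <- ape::prop.part(phy)
  ntip <- length(phy$tip.label)
  out <- list()
  for (p in parts) {
    side <- sort(phy$tip.label[p])
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (labs[1] %in% side) side <- setdiff(labs, side)
    out[[length(out) + 1]] <- side
  }
  # for unrooted interpretation also drop splits equivalent to trivial ones
  unique(out)
}

#' Strict consensus of equally parsimonious trees
#'
#' Retains exactly the bipartitions present in every input tree; conflicting
#' regions collapse to polytomies.
#'
#' @param trees List of `phylo` trees on the same leaf set.
#' @return A `phylo` (possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  if (!length(trees)) stop("need at least one tree", call. = FALSE)
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(sets, identical, logical(1), sets[[1]]))) {
    stop("trees have mismatched leaf sets", call. = FALSE)
  }
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1)
}

#' Robinson-Foulds symmetric difference between two trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return Integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  b1 <- vapply(nontrivial_bipartitions(t1), paste, character(1),
               collapse = ",")
  b2 <- vapply(nontrivial_bipartitions(t2), paste, character(1),
               collapse = ",")
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Nonparametric bootstrap supports
#'
#' Characters are resampled with replacement per pseudoreplicate, a heuristic
#' search is run on each resampled matrix, and clade support is the percentage
#' of replicate best trees containing the clade. Returns the majority-rule
#' consensus of replicate trees with node labels holding supports in 0..100.
#'
#' @param m A [character_matrix()].
#' @param reps Number of pseudoreplicates.
#' @param seed Seed (resampling is reproducible given it).
#' @param max_trees Tie cap per replicate search (1 keeps only the first).
#' @return A `phylo` with `node.label` giving percent support.
#' @export
bootstrap_support <- function(m, reps = 100, seed = NULL, max_trees = 1) {
  stopifnot(reps >= 1)
  ntip <- length(m$taxa)
  ns <- length(m$alphabet)
  nchar_ <- length(m$characters)
  st <- tip_state_matrix(m, m$taxa)
  one_rep <- function() {
    w <- tabulate(sample.int(nchar_, nchar_, replace = TRUE), nchar_)
    start <- stepwise_addition_edge(st, ns, w)
    res <- tbr_search_cpp(start, ntip, st, ns, as.numeric(w), 1L, 10000L)
    edge_to_phylo(res$trees[[1]], m$taxa)
  }
  rep_trees <- if (is.null(seed)) {
    replicate(reps, one_rep(), simplify = FALSE)
  } else {
    withr::with_seed(seed, replicate(reps, one_rep(), simplify = FALSE))
  }
  class(rep_trees) <- "multiPhylo"
  cons <- ape::consensus(rep_trees, p = 0.5)
  counts <- ape::prop.clades(cons, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- round(100 * counts / reps, 1)
  cons
}

#' Root an unrooted tree with the hypothetical all-ancestral taxon
#'
#' Lundberg-style rooting: a hypothetical ancestor bearing every character's
#' ancestral state is attached in turn to each branch; the branch minimising
#' total tree length receives the root, and the ancestor leaf is then removed.
#' Ties are broken deterministically toward the first branch in postorder
#' enumeration and reported via the `tie` attribute.
#'
#' @param t Unrooted `phylo`.
#' @param m A polarized [character_matrix()] (`ancestral` present).
#' @return Rooted `phylo` with attributes `root_length` (length including the
#'   ancestor) and `tie`.
#' @export
root_with_ancestor <- function(t, m) {
  stopifnot(inherits(t, "phylo"), inherits(m, "character_matrix"))
  if (is.null(m$ancestral)) {
    stop("matrix is not polarized: call polarize() first", call. = FALSE)
  }
  anc_label <- "..ancestor.."
  states2 <- rbind(m$states[t$tip.label, , drop = FALSE], m$ancestral)
  rownames(states2) <- c(t$tip.label, anc_label)
  m2 <- character_matrix(states2, ordered = m$ordered, alphabet = m$alphabet)
  ntip <- length(t$tip.label)
  st <- tip_state_matrix(m2, rownames(states2))
  ns <- length(m$alphabet)
  w <- rep(1, ncol(st))
  phy <- ape::reorder.phylo(t, "postorder")
  edge <- phy$edge
  anc_tip <- ntip + 1L
  # tips in m2 are 1..ntip+1; internal ids of `edge` shift up by one
  shift <- function(x) ifelse(x > ntip, x + 1L, x)
  base_edge <- cbind(shift(edge[, 1]), shift(edge[, 2]))
  new_int <- max(base_edge) + 1L
  lens <- vapply(seq_len(nrow(base_edge)), function(k) {
    cand <- .insert_tip(base_edge, k, anc_tip, new_int)
    score_edge_cpp(cand, ntip + 1L, st, ns, w)
  }, numeric(1))
  best <- which(lens == min(lens))
  tie <- length(best) > 1
  if (tie) {
    message("ancestor attachment ties across ", length(best),
            " branches; first in postorder chosen")
  }
  k <- best[1]
  # root at the attachment point: subdivide edge k with the new node and
  # orient everything away from it
  cand <- .insert_tip(base_edge, k, anc_tip, new_int)
  cand <- cand[!(cand[, 2] == anc_tip), , drop = FALSE] # prune ancestor leaf
  rooted <- orient_edges_from(cand, new_int)
  out <- edge_to_phylo(rooted, t$tip.label)
  attr(out, "root_length") <- min(lens)
  attr(out, "tie") <- tie
  out
}

# orient an undirected edge list away from a chosen root node
orient_edges_from <- function(edge, root) {
  adj <- list()
  add <- function(a, b) {
    key <- as.character(a)
    adj[[key]] <<- c(adj[[key]], b)
  }
  for (k in seq_len(nrow(edge))) {
    add(edge[k, 1], edge[k, 2])
    add(edge[k, 2], edge[k, 1])
  }
  out <- matrix(0L, nrow(edge), 2)
  r <- 0L
  seen <- c(root)
  stack <- c(root)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (v in adj[[as.character(u)]]) {
      if (!v %in% seen) {
        r <- r + 1L
        out[r, ] <- c(u, v)
        seen <- c(seen, v)
        stack <- c(stack, v)
      }
    }
  }
  out[seq_len(r), , drop = FALSE]
}

#' Minimum-cost ancestral state reconstruction
#'
#' Sankoff backtrace on a rooted tree: bottom-up cost vectors under ordered
#' |i-j| costs, then a top-down pass choosing, at each node, the state
#' minimising its own cost plus the distance to the parent's chosen state
#' (ties to the smallest state). The implied total cost equals
#' [tree_length()].
#'
#' @param t Rooted `phylo`.
#' @param m A [character_matrix()].
#' @return List with `states` (node x character symbol matrix over tips then
#'   internal nodes, ape numbering) and `cost` (total implied steps).
#' @export
ancestral_states <- function(t, m) {
  stopifnot(inherits(t, "phylo"))
  ntip <- length(t$tip.label)
  ns <- length(m$alphabet)
  st <- tip_state_matrix(m, t$tip.label)
  nchar_ <- ncol(st)
  phy <- ape::reorder.phylo(t, "postorder")
  nnode <- ntip + phy$Nnode
  root <- phy$edge[nrow(phy$edge), 1]
  BIG <- 1e9
  assign_states <- matrix(NA_integer_, nnode, nchar_)
  total <- 0
  dt <- function(g) {
    for (i in seq2(2L, ns)) g[i] <- min(g[i], g[i - 1] + 1)
    for (i in rev(seq2(1L, ns - 1L))) g[i] <- min(g[i], g[i + 1] + 1)
    g
  }
  for (cc in seq_len(nchar_)) {
    cost <- matrix(0, nnode, ns)
    for (i in seq_len(ntip)) {
      if (is.na(st[i, cc])) next
      cost[i, ] <- BIG
      cost[i, st[i, cc] + 1L] <- 0
    }
    for (k in seq_len(nrow(phy$edge))) {
      p <- phy$edge[k, 1]
      ch <- phy$edge[k, 2]
      cost[p, ] <- cost[p, ] + dt(cost[ch, ])
    }
    # top-down
    assign_states[root, cc] <- which.min(cost[root, ]) - 1L
    total <- total + min(cost[root, ])
    for (k in rev(seq_len(nrow(phy$edge)))) {
      p <- phy$edge[k, 1]
      ch <- phy$edge[k, 2]
      ps <- assign_states[p, cc]
      v <- cost[ch, ] + abs(seq_len(ns) - 1L - ps)
      assign_states[ch, cc] <- which.min(v) - 1L
    }
  }
  sym <- matrix(m$alphabet[assign_states + 1L], nnode, nchar_)
  colnames(sym) <- m$characters
  rownames(sym) <- c(t$tip.label, paste0("node", seq_len(phy$Nnode) + ntip))
  list(states = sym, cost = total)
}
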